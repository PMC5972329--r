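test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(mutation_rate = -1), "rates")
  expect_error(sim_config(transition_prob = 1.5), "transition_prob")
  expect_error(sim_config(allele_ratio = 0), "allele_ratio")
  expect_error(sim_config(composition = c(A = 0, C = 0, G = 0, T = 0)),
               "composition")
  # hazard above 1 is a config error at simulation time
  bad <- sim_config(mutation_rate = 0.3, base_bias = c(A = 5, C = 1, G = 1, T = 1))
  expect_error(simulate_repertoire(bad), "hazard")
})

test_that("references and repertoires are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 9, n_clones = 10)
  r1 <- make_reference(cfg); r2 <- make_reference(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_repertoire(cfg); s2 <- simulate_repertoire(cfg)
  expect_identical(s1$clones, s2$clones)
  expect_identical(s1$truth_mutations, s2$truth_mutations)
  s3 <- simulate_repertoire(sim_config(seed = 10, n_clones = 10))
  expect_false(identical(s1$clones$sequence, s3$clones$sequence))
})

test_that("heterozygous references differ exactly at the diagnostic positions", {
  cfg <- sim_config(seed = 12, heterozygous = TRUE, n_diagnostic = 3)
  ref <- make_reference(cfg)
  a <- strsplit(ref$c_a, "")[[1]]; b <- strsplit(ref$c_b, "")[[1]]
  expect_equal(which(a != b) - 1L, ref$diagnostic_positions)
  expect_length(ref$diagnostic_positions, 3)
})

test_that("zero mutation rate returns clones equal to their templates", {
  cfg <- sim_config(seed = 13, n_clones = 12, mutation_rate = 0,
                    indel_rate = 0)
  sim <- simulate_repertoire(cfg)
  expect_identical(sim$clones$sequence, sim$truth_clones$template)
  expect_equal(nrow(sim$truth_mutations), 0)
})

test_that("planted event totals follow the binomial expectation", {
  cfg <- sim_config(seed = 14, n_clones = 200, v_length = 0, c_length = 999,
                    mutation_rate = 5e-3, indel_rate = 0,
                    junction_indel_range = 0)
  sim <- simulate_repertoire(cfg)
  n <- 200 * 999
  expected <- n * 5e-3
  sigma <- sqrt(n * 5e-3 * (1 - 5e-3))
  expect_lt(abs(nrow(sim$truth_mutations) - expected), 3 * sigma)
})

test_that("truth records are consistent with the emitted sequences", {
  cfg <- sim_config(seed = 15, n_clones = 15, indel_rate = 0)
  sim <- simulate_repertoire(cfg)
  for (i in seq_len(nrow(sim$clones))) {
    tpl <- strsplit(sim$truth_clones$template[i], "")[[1]]
    got <- strsplit(sim$clones$sequence[i], "")[[1]]
    diff <- which(tpl != got)
    tm <- sim$truth_mutations[
      sim$truth_mutations$clone_id == sim$clones$clone_id[i], ]
    expect_setequal(diff - 1L, tm$position)
    expect_equal(got[tm$position + 1L], tm$to)
  }
})

test_that("substitution calls on indel-free output match truth exactly", {
  cfg <- sim_config(seed = 16, n_clones = 40, v_length = 0, c_length = 600,
                    mutation_rate = 5e-3, indel_rate = 0)
  sim <- simulate_repertoire(cfg)
  rec <- call_mutations(sim$clones, germline_reference(sim$reference$c_a))
  cmp <- truth_compare(rec, sim)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 1)
})

test_that("substitution recall stays high in the presence of indels", {
  cfg <- sim_config(seed = 17, n_clones = 60, v_length = 0, c_length = 600,
                    mutation_rate = 4.5e-3, indel_rate = 2 / 48)
  sim <- simulate_repertoire(cfg)
  # call each clone against its own template (the truth coordinates)
  recs <- purrr::map_dfr(seq_len(nrow(sim$clones)), function(i) {
    call_mutations(sim$clones[i, ],
                   germline_reference(sim$truth_clones$template[i]))
  })
  cmp <- truth_compare(recs, sim)
  expect_gte(cmp$recall, 0.99)
})

test_that("heterozygous simulation recovers the planted genotype", {
  cfg <- sim_config(seed = 18, n_clones = 40, v_length = 0, c_length = 300,
                    heterozygous = TRUE, indel_rate = 0)
  sim <- simulate_repertoire(cfg)
  profiles <- dplyr::bind_rows(
    tibble::tibble(allotype_id = "A",
                   position = sim$reference$diagnostic_positions,
                   base = strsplit(sim$reference$c_a, "")[[1]][
                     sim$reference$diagnostic_positions + 1L]),
    tibble::tibble(allotype_id = "B",
                   position = sim$reference$diagnostic_positions,
                   base = strsplit(sim$reference$c_b, "")[[1]][
                     sim$reference$diagnostic_positions + 1L]))
  g <- genotype_allotypes(sim$clones, profiles)
  expect_setequal(c(g$allele1, g$allele2), c("A", "B"))
})

test_that("a planted AID multiplier raises the AID-linked mutation fraction", {
  base_cfg <- sim_config(seed = 19, n_clones = 150, v_length = 0,
                         c_length = 999, mutation_rate = 3e-3, indel_rate = 0)
  hot_cfg <- sim_config(seed = 19, n_clones = 150, v_length = 0,
                        c_length = 999, mutation_rate = 3e-3, indel_rate = 0,
                        motif_multipliers = c(AID_RGYW = 5, AID_WRCY = 5,
                                              WA = 1, TW = 1))
  frac_aid <- function(cfg) {
    sim <- simulate_repertoire(cfg)
    rec <- call_mutations(sim$clones, germline_reference(sim$reference$c_a))
    hits <- scan_motifs(sim$reference$c_a, c("AID_RGYW", "AID_WRCY"))
    ov <- motif_overlap(rec, hits)
    sum(ov$n_at_mutable) / ov$n_substitutions[1]
  }
  expect_gt(frac_aid(hot_cfg), 2 * frac_aid(base_cfg))
})

test_that("neutral R/S of called mutations matches the enumeration oracle", {
  cfg <- sim_config(seed = 20, n_clones = 200, v_length = 0, c_length = 300,
                    mutation_rate = 5e-3, indel_rate = 0,
                    transition_prob = 1 / 3)   # uniform over the 3 targets
  sim <- simulate_repertoire(cfg)
  rec <- call_mutations(sim$clones, germline_reference(sim$reference$c_a))
  nc <- oracle_neutral_rs(sim$reference$c_a)
  rs_expected <- (nc["replacement"] + nc["nonsense"]) / nc["synonymous"]
  subs <- rec[rec$event_class == "substitution", ]
  rs_seen <- sum(subs$effect %in% c("replacement", "nonsense")) /
    sum(subs$effect == "synonymous")
  expect_equal(unname(rs_seen), unname(rs_expected), tolerance = 0.25)
})
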