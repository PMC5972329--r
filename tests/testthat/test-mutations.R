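clone_tbl <- function(seqs, prefix = "c") {
  tibble::tibble(clone_id = paste0(prefix, seq_along(seqs)),
                 individual_id = "B4", tissue = "spleen", sequence = seqs)
}

test_that("substitutions classify by codon translation of the single change", {
  g <- germline_reference("ATGGAT")
  # pos 4 A->G: GAT (Asp) -> GGT (Gly), transition, replacement
  r1 <- call_mutations(clone_tbl("ATGGGT"), g)
  expect_equal(r1$position, 4L)
  expect_equal(r1$titv, "transition")
  expect_equal(r1$effect, "replacement")
  # pos 5 T->C: GAT -> GAC, both Asp: synonymous
  r2 <- call_mutations(clone_tbl("ATGGAC"), g)
  expect_equal(r2$effect, "synonymous")
  expect_equal(r2$titv, "transition")
  # Trp TGG -> TGA: nonsense
  r3 <- call_mutations(clone_tbl("ATGTGA"), germline_reference("ATGTGG"))
  expect_equal(r3$effect, "nonsense")
})

test_that("allelic positions are skipped and masked spans excluded", {
  g <- germline_reference(
    "ATGGATATG",
    allelic_positions = tibble::tibble(position = 4L, major_base = "A",
                                       minor_base = "G",
                                       minor_frequency = 0.5))
  r <- call_mutations(clone_tbl("ATGGGTATG"), g)  # subs at 4 only
  expect_equal(nrow(r), 0)
  g2 <- germline_reference("ATGGATATG")
  r2 <- call_mutations(clone_tbl("ATGGGTATG"), g2,
                       masked_spans = tibble::tibble(start = 3L, end = 6L))
  expect_equal(nrow(r2), 0)
  expect_equal(attr(r2, "surveyed")$n_bp, 6L)  # masked bases not surveyed
})

test_that("substitutions downstream of a frameshift become noncoding", {
  ref <- "ATGAAACCCGGGTTTAAACCCGGGTTTAAA"
  clone <- ref
  substr(clone, 23, 23) <- "T"            # downstream substitution G->T
  clone <- paste0(substr(clone, 1, 6), substr(clone, 8, 30))  # del at pos 6
  r <- call_mutations(clone_tbl(clone), germline_reference(ref))
  expect_setequal(r$event_class, c("deletion", "substitution"))
  sub <- r[r$event_class == "substitution", ]
  expect_equal(sub$effect, "noncoding")
  del <- r[r$event_class == "deletion", ]
  expect_equal(del$effect, "frameshift")
})

test_that("classification agrees with full-translation oracle (<=1 sub/codon)", {
  set.seed(101)
  ref <- random_dna(300)
  g <- germline_reference(ref)
  for (i in 1:50) {
    pos <- sample(0:299, 1)
    from <- substr(ref, pos + 1, pos + 1)
    to <- sample(setdiff(c("A", "C", "G", "T"), from), 1)
    clone <- ref
    substr(clone, pos + 1, pos + 1) <- to
    r <- call_mutations(clone_tbl(clone), g)
    expect_equal(r$effect, oracle_effect(ref, pos, to),
                 info = paste("pos", pos, from, ">", to))
  }
})

test_that("summary reproduces report-table accounting identities", {
  rec <- make_record_fixture(n_repl_ti = 5, n_repl_tv = 1,
                             n_silent_ti = 2, n_silent_tv = 0,
                             n_frameshift = 2)
  s <- summarize_mutations(rec, n_bp = 5690, n_clones = 18, label = "B1")
  expect_equal(s$n_events, 10)
  expect_equal(s$replacement + s$silent + s$frameshifts, s$n_events)
  expect_equal(s$transitions + s$transversions + s$frameshifts, s$n_events)
  expect_equal(printed_value(s$freq_per_kb, 2), 1.75)
  expect_error(summarize_mutations(rec, n_bp = 0), "positive")
  # zero events: frequency 0, ratios NA
  s0 <- summarize_mutations(rec[0, ], n_bp = 1000)
  expect_equal(s0$freq_per_kb, 0)
  expect_true(is.na(s0$rs_ratio) && is.na(s0$titv_ratio))
})

test_that("window profile: direct formula, masking, and count conservation", {
  rec <- tibble::tibble(
    clone_id = c("c1", "c2", "c3"), position = c(5L, 12L, 30L),
    from_base = "A", to_base = "G", event_class = "substitution",
    length = 1L, titv = "transition",
    effect = c("replacement", "replacement", "synonymous"),
    region = NA_character_)
  w <- window_profile(rec, n_clones = 48, ref_length = 40, window = 20)
  r1 <- w[w$window_start == 0 & w$class == "replacement", ]
  expect_equal(r1$count, 2)
  expect_equal(r1$frequency, 2 / (20 * 48))
  # conservation: sum of counts equals number of unmasked substitutions
  expect_equal(sum(w$count), 3)
  # masked primer span removes its events everywhere
  wm <- window_profile(rec, n_clones = 48, ref_length = 40, window = 20,
                       masked_spans = tibble::tibble(start = 0L, end = 9L))
  expect_equal(sum(wm$count), 2)
  expect_error(window_profile(rec, 48, 40, window = 0), "window")
})

test_that("no-event profile is all zero", {
  rec <- make_record_fixture(0, 0, 0, 0)
  w <- window_profile(rec, n_clones = 10, ref_length = 60, window = 20)
  expect_true(all(w$count == 0))
  expect_true(all(w$frequency == 0))
})

test_that("functional status separates in-frame, stop and frameshift clones", {
  ref <- paste0("ATG", strrep("GCT", 20), "TAA")   # clean ORF
  g <- germline_reference(ref)
  stop_clone <- ref
  substr(stop_clone, 10, 12) <- "TAA"
  fs_clone <- paste0(substr(ref, 1, 30), substr(ref, 32, nchar(ref)))
  st <- functional_status(clone_tbl(c(ref, stop_clone, fs_clone)), g)
  expect_equal(st$status, c("in_frame", "stop_codon", "frameshift"))
  # a 48-clone set with 1 stop + 2 frameshifts is 6.25% non-functional
  statuses <- c(rep("in_frame", 45), "stop_codon", "frameshift", "frameshift")
  expect_equal(nonfunctional_fraction(statuses), 0.0625)
})

test_that("rate contrast: ratio, symmetry and degenerate inputs", {
  cr <- compare_rates(16, 6952, 8, 12992)
  expect_equal(cr$ratio, (16 / 6952) / (8 / 12992), tolerance = 1e-12)
  expect_equal(round(cr$ratio, 2), 3.74)
  eq <- compare_rates(5, 1000, 5, 1000)
  expect_equal(eq$ratio, 1)
  expect_gt(eq$p_value, 0.9)
  z <- compare_rates(10, 1000, 0, 1000)
  expect_true(is.na(z$ratio))
  expect_match(z$note, "zero control")
  z2 <- compare_rates(0, 1000, 0, 1000)
  expect_true(is.na(z2$ratio) && is.na(z2$p_value))
})

test_that("short clones survey only their aligned span with a warning", {
  set.seed(5)
  ref <- random_dna(100)
  frag <- substr(ref, 31, 60)
  expect_warning(r <- call_mutations(clone_tbl(frag), germline_reference(ref)),
                 "fragment")
  expect_equal(attr(r, "surveyed")$n_bp, 30L)
})
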