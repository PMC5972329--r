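make_pool <- function(seqs, prefix = "c") {
  tibble::tibble(
    clone_id = paste0(prefix, seq_along(seqs)),
    individual_id = "B4", tissue = "spleen", sequence = seqs)
}

test_that("alignment: identity, substitution, and indel with flanks", {
  al <- align_clone("ACGT", "ACGT")
  expect_equal(nrow(al$events), 0)
  expect_equal(al$score, 4)
  expect_equal(al$surveyed_bp, 4)

  al <- align_clone("ACGT", "AGGT")
  expect_equal(al$events$event_class, "substitution")
  expect_equal(al$events$ref_start, 1L)
  expect_equal(al$events$from_base, "G")
  expect_equal(al$events$to_base, "C")

  ref <- "AAACCCGGGTTTATGGATAAACCCGGGTTT"
  clone <- sub("ATGGAT", "ATGAT", ref)
  al <- align_clone(clone, ref)
  expect_equal(al$events$event_class, "deletion")
  expect_equal(al$events$length, 1L)
})

test_that("alignment score is symmetric and N columns are excluded", {
  s1 <- "ACGTACGTAC"; s2 <- "ACGTTCGTAC"
  expect_equal(align_clone(s1, s2)$score, align_clone(s2, s1)$score)
  al <- align_clone("ACNT", "ACGT")
  expect_equal(nrow(al$events), 0)     # N never yields an event
  expect_equal(al$surveyed_bp, 3)
})

test_that("germline inference recovers consensus and 50/50 allelic columns", {
  base <- strrep("ACGT", 5)
  hapA <- base
  hapB <- base
  substr(hapB, 3, 3) <- "T"   # position 2 (0-based): G -> T
  pool <- make_pool(c(rep(hapA, 3), rep(hapB, 3)))
  g <- infer_germline(pool)
  expect_equal(nrow(g$allelic_positions), 1)
  expect_equal(g$allelic_positions$position, 2L)
  expect_equal(g$allelic_positions$minor_frequency, 0.5)

  # low-frequency minority base is a mutation, not an allele
  mut <- hapA
  substr(mut, 5, 5) <- "G"
  pool2 <- make_pool(c(rep(hapA, 5), mut))
  g2 <- infer_germline(pool2)
  expect_equal(nrow(g2$allelic_positions), 0)
  expect_equal(g2$sequence, hapA)
})

test_that("germline inference guards: pool size and three-way ties", {
  pool <- make_pool(rep("ACGT", 3))
  expect_error(infer_germline(pool), "insufficient")
  pool3 <- make_pool(c("AAAA", "AAAC", "AAAG", "AAAC", "AAAG", "AAAA"))
  expect_error(infer_germline(pool3), "three-way tie")
})

test_that("two planted subgroups split by allelic haplotype only", {
  base <- strrep("GATTACAT", 6)
  hapA <- base; hapB <- base
  substr(hapB, 11, 11) <- "G"; substr(hapB, 31, 31) <- "C"
  mutated <- hapA
  substr(mutated, 20, 20) <- "C"   # somatic mutation, not allelic
  pool <- make_pool(c(rep(hapA, 4), rep(hapB, 4), mutated))
  g <- infer_germline(pool)
  expect_equal(g$allelic_positions$position, c(10L, 30L))
  sp <- split_subgroups(pool, g)
  expect_equal(length(unique(sp$clones$subgroup)), 2)
  # the mutated clone stays with its haplotype
  expect_equal(sp$clones$subgroup[9], sp$clones$subgroup[1])
  # each subgroup reference carries its own haplotype bases
  ref_of <- function(cl) sp$references$sequence[
    sp$references$subgroup == sp$clones$subgroup[cl]]
  expect_equal(substr(ref_of(1), 11, 11), substr(hapA, 11, 11))
  expect_equal(substr(ref_of(5), 11, 11), "G")
})

test_that("zero allelic positions yields a single subgroup", {
  pool <- make_pool(rep(strrep("ACGT", 4), 5))
  g <- infer_germline(pool)
  sp <- split_subgroups(pool, g)
  expect_equal(unique(sp$clones$subgroup), "all")
})

test_that("allelic differences are never called as somatic mutations", {
  set.seed(42)
  cfg <- sim_config(seed = 42, n_clones = 30, heterozygous = TRUE,
                    v_length = 0, c_length = 300, indel_rate = 0,
                    mutation_rate = 3e-3)
  sim <- simulate_repertoire(cfg)
  g <- infer_germline(sim$clones)
  sp <- split_subgroups(sim$clones, g)
  diag_pos <- sim$reference$diagnostic_positions
  expect_setequal(g$allelic_positions$position, diag_pos)
  resolved <- sp$clones[!is.na(sp$clones$subgroup), ]
  truth_keys <- with(sim$truth_mutations, paste(clone_id, position))
  for (sg in unique(resolved$subgroup)) {
    rec <- call_mutations(
      resolved[resolved$subgroup == sg, ],
      germline_reference(sp$references$sequence[sp$references$subgroup == sg]))
    at_diag <- rec[rec$position %in% diag_pos, ]
    # any call at a diagnostic position must be a planted somatic event,
    # never the allelic difference itself
    expect_true(all(paste(at_diag$clone_id, at_diag$position) %in% truth_keys))
  }
})

test_that("allotype genotyping matches profile support patterns", {
  profiles <- tibble::tibble(
    allotype_id = rep(c("A", "B", "F"), each = 2),
    position = c(5L, 20L, 5L, 20L, 5L, 20L),
    base = c("A", "C", "G", "C", "G", "T"))
  base <- strrep("T", 30)
  seq_of <- function(b5, b20) {
    s <- base; substr(s, 6, 6) <- b5; substr(s, 21, 21) <- b20; s
  }
  het <- make_pool(c(rep(seq_of("A", "C"), 5), rep(seq_of("G", "C"), 5)))
  gAB <- genotype_allotypes(het, profiles)
  expect_equal(c(gAB$allele1, gAB$allele2), c("A", "B"))
  hom <- make_pool(rep(seq_of("G", "C"), 8))
  gBB <- genotype_allotypes(hom, profiles)
  expect_equal(c(gBB$allele1, gBB$allele2), c("B", "B"))
  single <- make_pool(seq_of("G", "T"))
  gFF <- genotype_allotypes(single, profiles)
  expect_equal(c(gFF$allele1, gFF$allele2), c("F", "F"))
  expect_true(gFF$low_support)
  novel <- make_pool(c(rep(seq_of("A", "C"), 4), seq_of("T", "G")))
  gN <- genotype_allotypes(novel, profiles, max_mismatch = 1)
  expect_equal(gN$n_novel, 1)
})

test_that("chimera verdicts follow the single-crossover rule", {
  refA <- "AAAAAAAAAAAAAAAAAAAA"
  refB <- "ACAACAACAACAACAACAAC"   # diagnostics at many positions
  diag <- which(strsplit(refA, "")[[1]] != strsplit(refB, "")[[1]])
  mk <- function(pattern) {
    s <- strsplit(refA, "")[[1]]
    b <- strsplit(refB, "")[[1]]
    for (i in seq_along(diag)) if (pattern[i] == "B") s[diag[i]] <- b[diag[i]]
    paste(s, collapse = "")
  }
  n <- length(diag)
  chim <- mk(c(rep("A", 3), rep("B", n - 3)))
  inter <- mk(rep_len(c("A", "B"), n))
  pure <- mk(rep("A", n))
  v <- flag_chimeras(make_pool(c(chim, inter, pure)), c(refA, refB))
  expect_equal(v$verdict, c("chimera", "not_chimera", "not_chimera"))
  # fewer than 4 diagnostic positions is untestable
  refC <- refA; substr(refC, 2, 2) <- "G"; substr(refC, 12, 12) <- "G"
  v2 <- flag_chimeras(make_pool(refA), c(refA, refC))
  expect_equal(v2$verdict, "untestable")
})

test_that("V-family clustering: threshold, single linkage, label stability", {
  set.seed(7)
  a <- random_dna(120)
  mutate_n <- function(s, n) {
    x <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(x), n)
    for (i in idx) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
    paste(x, collapse = "")
  }
  near <- mutate_n(a, 12)      # 90% identical to a
  far <- random_dna(120)       # ~25% identical
  fam <- cluster_v_families(make_pool(c(a, near, far)))
  expect_equal(fam$family[1], fam$family[2])
  expect_false(fam$family[3] == fam$family[1])

  # transitive chain joins via single linkage: a~b and b~c >= 0.75
  b <- mutate_n(a, 25)
  c_ <- mutate_n(b, 25)
  fam2 <- cluster_v_families(make_pool(c(a, b, c_)))
  expect_equal(length(unique(fam2$family)), 1)

  # permutation invariance up to renaming
  pool <- make_pool(c(a, near, far, b))
  f1 <- cluster_v_families(pool)
  perm <- pool[c(3, 1, 4, 2), ]
  f2 <- cluster_v_families(perm)
  j <- dplyr::inner_join(f1, f2, by = "clone_id")
  tab <- table(j$family.x, j$family.y)
  expect_true(all(colSums(tab > 0) == 1) && all(rowSums(tab > 0) == 1))
})

test_that("J assignment finds exact copies and honors tie/threshold rules", {
  set.seed(11)
  jlib <- tibble::tibble(
    j_id = c("J01", "J02", "J03"),
    sequence = c(random_dna(30), random_dna(30), random_dna(30)))
  clone <- paste0(random_dna(60), jlib$sequence[2], random_dna(40))
  res <- assign_j_segment(make_pool(clone), jlib)
  expect_equal(res$j_id, "J02")
  expect_equal(res$score, 30)
  expect_equal(res$j_start, 60)

  none <- make_pool(strrep("A", 150))
  jlib_gc <- tibble::tibble(j_id = "J01", sequence = strrep("GC", 15))
  expect_true(is.na(assign_j_segment(none, jlib_gc)$j_id))

  dup <- tibble::tibble(j_id = c("Jx", "Jy"),
                        sequence = rep(jlib$sequence[1], 2))
  res2 <- assign_j_segment(make_pool(paste0(random_dna(20), jlib$sequence[1])),
                           dup)
  expect_equal(res2$j_id, "Jx")   # lowest library index wins ties
})
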