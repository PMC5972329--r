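# Germline and allele inference: consensus reference, allelic (allotypic)
# positions, subgroup splitting, constant-region allotype genotyping,
# PCR-jumping chimera detection, V-family clustering and J assignment.

#' Construct a germline reference object
#'
#' @param sequence Reference nucleotide string.
#' @param allelic_positions Tibble with columns `position` (0-based),
#'   `major_base`, `minor_base`, `minor_frequency` (in (0, 0.5]).
#' @param frame_offset Integer 0-2.
#' @param source `"supplied"` or `"inferred"`.
#' @return Object of class `shm_germline`.
#' @export
germline_reference <- function(sequence,
                               allelic_positions = NULL,
                               frame_offset = 0L,
                               source = "supplied") {
  if (is.null(allelic_positions)) {
    allelic_positions <- tibble::tibble(
      position = integer(0), major_base = character(0),
      minor_base = character(0), minor_frequency = numeric(0)
    )
  }
  if (nrow(allelic_positions)) {
    if (any(allelic_positions$position < 0 |
            allelic_positions$position >= nchar(sequence))) {
      stop_shm("allelic position outside reference")
    }
    if (any(allelic_positions$minor_frequency <= 0 |
            allelic_positions$minor_frequency > 0.5)) {
      stop_shm("minor_frequency must lie in (0, 0.5]")
    }
  }
  structure(
    list(sequence = sequence, allelic_positions = allelic_positions,
         frame_offset = as.integer(frame_offset),
         source = match.arg(source, c("supplied", "inferred"))),
    class = "shm_germline"
  )
}

#' @export
print.shm_germline <- function(x, ...) {
  cat("<shm_germline> ", nchar(x$sequence), " nt, source = ", x$source,
      ", ", nrow(x$allelic_positions), " allelic position(s)\n", sep = "")
  invisible(x)
}

# per-clone character matrix on a common coordinate system; clones whose
# length differs from the scaffold are projected through align_clone
clone_char_matrix <- function(clones, scaffold = NULL) {
  seqs <- clones$sequence
  if (is.null(scaffold)) {
    lens <- nchar(seqs)
    modal <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    scaffold <- seqs[lens == modal][1]
  }
  L <- nchar(scaffold)
  mat <- matrix(NA_character_, nrow = length(seqs), ncol = L)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == L) {
      # already on the common coordinate system; ends-free alignment would
      # shed terminal substitutions as overhangs
      mat[i, ] <- seq_chars(seqs[i])
    } else {
      al <- align_clone(seqs[i], scaffold)
      cols <- al$columns
      keep <- !is.na(cols$ref_pos) & cols$clone_base != "-"
      mat[i, cols$ref_pos[keep] + 1L] <- cols$clone_base[keep]
    }
  }
  mat
}

#' Infer a germline reference from a clone pool
#'
#' The consensus base of each column becomes the reference. Columns whose
#' second most frequent base reaches `allele_threshold` (of non-N calls) are
#' recorded as allelic positions — the two-allele (~50/50) signature — and
#' are excluded from somatic-mutation calling downstream. Minority bases
#' below the threshold are left to be called as mutations.
#'
#' @param clones Clone tibble (>= 4 clones).
#' @param allele_threshold Minor-base frequency at or above which a column
#'   is treated as allelic rather than mutated (default 0.3).
#' @param frame_offset Reading-frame offset of the reference.
#' @return An `shm_germline` with `source = "inferred"`.
#' @export
infer_germline <- function(clones, allele_threshold = 0.3, frame_offset = 0L) {
  check_clone_tbl(clones)
  if (nrow(clones) < 4) {
    stop_shm("insufficient data: germline inference needs >= 4 clones, got ",
             nrow(clones))
  }
  mat <- clone_char_matrix(clones)
  L <- ncol(mat)
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b, na.rm = TRUE),
                   numeric(L))
  if (L == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, DNA_BASES))
  totals <- rowSums(counts)
  if (any(totals == 0)) stop_shm("column(s) with no A/C/G/T calls")
  ord <- t(apply(counts, 1, order, decreasing = TRUE))
  top1 <- counts[cbind(seq_len(L), ord[, 1])]
  top2 <- counts[cbind(seq_len(L), ord[, 2])]
  top3 <- counts[cbind(seq_len(L), ord[, 3])]
  amb <- which(top3 > 0 & top3 == top1)
  if (length(amb)) {
    stop_shm("ambiguous consensus (three-way tie) at column(s): ",
             paste(amb - 1L, collapse = ", "))
  }
  # ties between the top two resolved alphabetically (order() is stable)
  major <- DNA_BASES[ord[, 1]]
  minor <- DNA_BASES[ord[, 2]]
  minor_freq <- top2 / totals
  allelic <- which(top2 > 0 & minor_freq >= allele_threshold)
  germline_reference(
    sequence = paste(major, collapse = ""),
    allelic_positions = tibble::tibble(
      position = allelic - 1L,
      major_base = major[allelic],
      minor_base = minor[allelic],
      minor_frequency = pmin(minor_freq[allelic], 0.5)
    ),
    frame_offset = frame_offset,
    source = "inferred"
  )
}

#' Split a clone pool into allelic-haplotype subgroups
#'
#' Clones are partitioned by the combination of bases they carry at the
#' germline's allelic positions (and by those positions only, mirroring the
#' treatment of near-identical V-gene subgroups). Each subgroup receives its
#' own per-haplotype reference so that allelic differences are never counted
#' as somatic mutations. Clones whose bases at the allelic positions match
#' no cleanly observed haplotype best — or tie between two — are flagged
#' `unresolved` and excluded.
#'
#' @param clones Clone tibble.
#' @param germline `shm_germline` from [infer_germline()].
#' @return List with `clones` (input tibble plus `subgroup` column, NA for
#'   unresolved) and `references` (tibble `subgroup`, `sequence` of the
#'   per-haplotype reference).
#' @export
split_subgroups <- function(clones, germline) {
  check_clone_tbl(clones)
  ap <- germline$allelic_positions
  if (nrow(ap) == 0) {
    refs <- tibble::tibble(subgroup = "all", sequence = germline$sequence)
    return(list(clones = dplyr::mutate(clones, subgroup = "all"),
                references = refs))
  }
  mat <- clone_char_matrix(clones, scaffold = germline$sequence)
  obs <- mat[, ap$position + 1L, drop = FALSE]
  allowed <- rbind(ap$major_base, ap$minor_base)
  clean <- vapply(seq_len(nrow(obs)), function(i) {
    all(obs[i, ] == allowed[1, ] | obs[i, ] == allowed[2, ])
  }, logical(1))
  hap_of <- function(i) paste(obs[i, ], collapse = "")
  haplos <- vapply(seq_len(nrow(obs)), hap_of, character(1))
  candidates <- unique(haplos[clean])
  subgroup <- rep(NA_character_, nrow(obs))
  subgroup[clean] <- haplos[clean]
  # clones with a non-allelic base at an allelic position: nearest candidate
  for (i in which(!clean)) {
    d <- vapply(candidates, function(h) {
      sum(seq_chars(h) != obs[i, ])
    }, numeric(1))
    best <- which(d == min(d))
    if (length(best) == 1) subgroup[i] <- candidates[best]
  }
  refs <- purrr::map_dfr(sort(unique(stats::na.omit(subgroup))), function(h) {
    s <- seq_chars(germline$sequence)
    s[ap$position + 1L] <- seq_chars(h)
    tibble::tibble(subgroup = h, sequence = paste(s, collapse = ""))
  })
  list(clones = dplyr::mutate(clones, subgroup = subgroup), references = refs)
}

#' Read constant-region allotype profiles from TSV
#'
#' Columns: `allotype_id`, `position_1based`, `base`. Positions are
#' converted to the internal 0-based convention.
#'
#' @param path TSV path.
#' @return Tibble `allotype_id`, `position`, `base`.
#' @export
read_allotype_profiles <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::tibble(
    allotype_id = x$allotype_id,
    position = as.integer(x$position_1based) - 1L,
    base = toupper(x$base)
  )
}

#' Genotype constant-region allotypes for one individual
#'
#' Each clone's constant-region sequence is assigned to the allotype profile
#' with the fewest mismatches at the diagnostic positions (ties are left
#' unassigned; clones beyond `max_mismatch` become novel-allotype
#' candidates). The genotype is the one or two profiles with support;
#' a homozygous call requires the top profile to explain at least
#' `hom_threshold` of assignable clones.
#'
#' @param clones Clone tibble of constant-region sequences (one individual;
#'   sequences must cover all diagnostic positions).
#' @param profiles Profile tibble (`allotype_id`, `position` 0-based,
#'   `base`), e.g. from [read_allotype_profiles()].
#' @param max_mismatch Diagnostic mismatches tolerated in an assignment
#'   (default 1).
#' @param hom_threshold Fraction of assignable clones one profile must
#'   explain for a homozygous call (default 0.95).
#' @return One-row tibble: `individual_id`, `allele1`, `allele2`,
#'   `n_assigned`, `n_unassigned`, `n_novel`, `low_support`, plus a
#'   `support` list-column of per-allotype clone counts.
#' @export
genotype_allotypes <- function(clones, profiles, max_mismatch = 1,
                               hom_threshold = 0.95) {
  check_clone_tbl(clones)
  ids <- unique(profiles$allotype_id)
  if (length(ids) < 1) stop_shm("no allotype profiles supplied")
  need <- max(profiles$position) + 1L
  if (any(nchar(clones$sequence) < need)) {
    stop_shm("sequence(s) do not cover all diagnostic positions")
  }
  mm <- vapply(ids, function(a) {
    p <- profiles[profiles$allotype_id == a, ]
    vapply(clones$sequence, function(s) {
      sum(substring(s, p$position + 1L, p$position + 1L) != p$base)
    }, numeric(1), USE.NAMES = FALSE)
  }, numeric(nrow(clones)))
  mm <- matrix(mm, nrow = nrow(clones), dimnames = list(NULL, ids))
  assign <- rep(NA_character_, nrow(clones))
  novel <- logical(nrow(clones))
  for (i in seq_len(nrow(clones))) {
    best <- which(mm[i, ] == min(mm[i, ]))
    if (min(mm[i, ]) > max_mismatch) {
      novel[i] <- TRUE
    } else if (length(best) == 1) {
      assign[i] <- ids[best]
    } # tie -> unassigned
  }
  support <- table(factor(assign, levels = ids))
  assigned <- sum(support)
  supported <- names(support)[support > 0]
  supported <- supported[order(-support[supported])]
  if (length(supported) == 0) {
    allele1 <- allele2 <- NA_character_
  } else if (length(supported) == 1 ||
             support[supported[1]] / assigned >= hom_threshold) {
    allele1 <- allele2 <- supported[1]
  } else {
    pair <- sort(supported[1:2])
    allele1 <- pair[1]; allele2 <- pair[2]
  }
  ind <- if ("individual_id" %in% names(clones) &&
             any(nzchar(clones$individual_id))) {
    clones$individual_id[nzchar(clones$individual_id)][1]
  } else ""
  tibble::tibble(
    individual_id = ind, allele1 = allele1, allele2 = allele2,
    n_assigned = assigned, n_unassigned = sum(is.na(assign) & !novel),
    n_novel = sum(novel),
    low_support = assigned < 2,
    support = list(tibble::tibble(allotype_id = ids,
                                  n_clones = as.integer(support)))
  )
}

#' Flag PCR-jumping chimeras in a heterozygous individual
#'
#' A clone is a chimera when its bases at the positions distinguishing the
#' two allele references form a single-crossover pattern: a 5' run matching
#' one allele followed by a 3' run matching the other, each run covering at
#' least two diagnostic sites. Interleaved patterns are treated as
#' mutations, not chimeras. Fewer than 4 diagnostic positions make the test
#' `untestable`.
#'
#' @param clones Clone tibble.
#' @param allele_refs Character vector of the two allele reference
#'   sequences (equal length).
#' @return Tibble `clone_id`, `verdict` in
#'   `{"chimera","not_chimera","untestable"}`.
#' @export
flag_chimeras <- function(clones, allele_refs) {
  check_clone_tbl(clones)
  if (length(allele_refs) != 2 || nchar(allele_refs[1]) != nchar(allele_refs[2])) {
    stop_shm("allele_refs must be two equal-length sequences")
  }
  a <- seq_chars(allele_refs[1]); b <- seq_chars(allele_refs[2])
  diag_pos <- which(a != b)  # 1-based
  verdicts <- vapply(clones$sequence, function(s) {
    if (length(diag_pos) < 4) return("untestable")
    x <- substring(s, diag_pos, diag_pos)
    lab <- ifelse(x == a[diag_pos], "A", ifelse(x == b[diag_pos], "B", "."))
    lab <- lab[lab != "."]
    if (length(lab) < 4) return("untestable")
    r <- rle(lab)
    if (length(r$values) == 2 && all(r$lengths >= 2)) "chimera" else "not_chimera"
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(clone_id = clones$clone_id, verdict = verdicts)
}

#' Cluster V sequences into families by nucleotide identity
#'
#' Single-linkage clustering on pairwise global-alignment identity
#' (matches / aligned columns, terminal gaps excluded). Families are
#' numbered `V1`, `V2`, ... by decreasing size, ties by first occurrence.
#'
#' @param clones Clone tibble of V-region sequences.
#' @param identity_threshold Linkage threshold (default 0.75).
#' @return Input tibble with a `family` column added.
#' @export
cluster_v_families <- function(clones, identity_threshold = 0.75) {
  check_clone_tbl(clones)
  n <- nrow(clones)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (pairwise_identity(clones$sequence[i], clones$sequence[j]) >=
          identity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  lab <- stats::setNames(paste0("V", seq_along(ord)), names(sizes)[ord])
  dplyr::mutate(clones, family = unname(lab[as.character(roots)]))
}

#' Pairwise nucleotide identity of two sequences
#'
#' Matches divided by aligned columns after a full global alignment,
#' excluding terminal gap columns. (Family clustering needs the whole-gene
#' identity; the ends-free clone aligner would let a short high-identity
#' overlap masquerade as global similarity.)
#'
#' @param s1,s2 Nucleotide strings.
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(s1, s2) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(s1),
    subject = Biostrings::DNAString(s2),
    type = "global", substitutionMatrix = shm_submat(),
    gapOpening = 3, gapExtension = 1
  )
  a <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  inner <- which(a != "-" & b != "-")
  if (length(inner) == 0) return(0)
  span <- inner[1]:inner[length(inner)]
  sum(a[span] == b[span]) / length(span)
}

#' Assign the best-matching J segment to each clone
#'
#' Each library J is slid ungapped along the clone 3' of `search_from`;
#' the best offset maximizes matches - mismatches. Clones whose best J
#' achieves fewer than `min_match_frac` of the J length as matches are
#' unassigned. Score ties break toward the lowest library index.
#'
#' @param clones Clone tibble.
#' @param j_library Tibble `j_id`, `sequence` (5'-to-3' order).
#' @param min_match_frac Minimum matched fraction of the J length
#'   (default 0.8).
#' @param search_from 0-based clone position where the search starts
#'   (end of the V region if known; default 0).
#' @return Tibble `clone_id`, `j_id` (NA if unassigned), `score`,
#'   `j_start` (0-based position on the clone).
#' @export
assign_j_segment <- function(clones, j_library, min_match_frac = 0.8,
                             search_from = 0L) {
  check_clone_tbl(clones)
  if (nrow(j_library) == 0) stop_shm("j_library is empty")
  jchars <- lapply(j_library$sequence, seq_chars)
  purrr::map_dfr(seq_len(nrow(clones)), function(ci) {
    x <- seq_chars(clones$sequence[ci])
    if (search_from > 0) x <- x[-seq_len(min(search_from, length(x)))]
    best <- list(score = -Inf, j = NA_integer_, off = NA_integer_, matches = 0L)
    for (ji in seq_along(jchars)) {
      j <- jchars[[ji]]
      m <- length(j)
      if (m > length(x)) next
      offs <- 0:(length(x) - m)
      idx <- outer(offs, seq_len(m), `+`)      # offsets x j-positions
      matches <- rowSums(matrix(x[idx] == rep(j, each = length(offs)),
                                nrow = length(offs)))
      sc <- 2L * matches - m
      top <- which.max(sc)                      # earliest offset on ties
      if (sc[top] > best$score) {
        best <- list(score = sc[top], j = ji, off = offs[top],
                     matches = matches[top])
      }
    }
    ok <- is.finite(best$score) &&
      best$matches >= min_match_frac * length(jchars[[best$j]])
    tibble::tibble(
      clone_id = clones$clone_id[ci],
      j_id = if (ok) j_library$j_id[best$j] else NA_character_,
      score = if (is.finite(best$score)) best$score else NA_integer_,
      j_start = if (ok) best$off + as.integer(search_from) else NA_integer_
    )
  })
}
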