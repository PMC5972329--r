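# Genomic J-segment discovery: candidate J exons are windows whose
# translation carries the conserved FGXG-like core, flanked 5' by a
# 12-spacer recombination signal sequence (nonamer-spacer-heptamer) and 3'
# by a GT splice donor. The RSS consensus sequences and mismatch budgets
# are the canonical operationalization and are all configurable.

#' J-segment scan configuration
#'
#' @param core_pattern Regex the translated exon must contain
#'   (default `"[FW]G.G"`, admitting slightly modified FGXG cores; use
#'   `"FG.G"` for the strict form).
#' @param exon_min,exon_max Exon length bounds in nt (default 36-75).
#' @param heptamer RSS heptamer consensus (default `"CACAGTG"`); the
#'   leading `CAC` is invariant.
#' @param heptamer_max_mm Mismatches allowed outside `CAC` (default 1).
#' @param nonamer RSS nonamer consensus (default `"ACAAAAACC"`).
#' @param nonamer_max_mm Mismatches allowed in the nonamer (default 2).
#' @param spacer_min,spacer_max Spacer band in nt (default 11-13, i.e.
#'   12 +/- 1; J segments conventionally carry a 12-RSS). Must lie within
#'   [10, 25].
#' @return List of class `shm_jscan_config`.
#' @export
jscan_config <- function(core_pattern = "[FW]G.G",
                         exon_min = 36L, exon_max = 75L,
                         heptamer = "CACAGTG", heptamer_max_mm = 1L,
                         nonamer = "ACAAAAACC", nonamer_max_mm = 2L,
                         spacer_min = 11L, spacer_max = 13L) {
  if (spacer_min < 10 || spacer_max > 25 || spacer_min > spacer_max) {
    stop_shm("spacer band must lie within [10, 25]")
  }
  structure(list(core_pattern = core_pattern,
                 exon_min = as.integer(exon_min),
                 exon_max = as.integer(exon_max),
                 heptamer = heptamer, heptamer_max_mm = as.integer(heptamer_max_mm),
                 nonamer = nonamer, nonamer_max_mm = as.integer(nonamer_max_mm),
                 spacer_min = as.integer(spacer_min),
                 spacer_max = as.integer(spacer_max)),
            class = "shm_jscan_config")
}

# scan one strand; coordinates local to `s`
scan_j_one_strand <- function(s, config) {
  x <- seq_chars(s)
  L <- length(x)
  hept <- seq_chars(config$heptamer)
  nona <- seq_chars(config$nonamer)
  hl <- length(hept); nl <- length(nona)
  # heptamer candidates: invariant CAC prefix, budget on the remainder
  starts <- which(x == hept[1])
  starts <- starts[starts + hl - 1L <= L - config$exon_min - 2L]
  out <- list()
  for (h in starts) {
    if (any(x[h:(h + 2L)] != hept[1:3])) next
    hseq <- x[h:(h + hl - 1L)]
    h_mm <- sum(hseq[4:hl] != hept[4:hl])
    if (h_mm > config$heptamer_max_mm) next
    # nonamer across the spacer band; keep the best (fewest mismatches,
    # then spacer closest to the band midpoint)
    best_n <- NULL
    for (sp in config$spacer_min:config$spacer_max) {
      ns <- h - sp - nl
      if (ns < 1) next
      n_mm <- sum(x[ns:(ns + nl - 1L)] != nona)
      if (n_mm > config$nonamer_max_mm) next
      if (is.null(best_n) || n_mm < best_n$mm) {
        best_n <- list(mm = n_mm, spacer = sp,
                       seq = paste(x[ns:(ns + nl - 1L)], collapse = ""))
      }
    }
    if (is.null(best_n)) next
    exon_start <- h + hl          # 1-based first exon base
    # maximal window: largest exon length with GT donor and in-frame core
    for (len in seq(config$exon_max, config$exon_min)) {
      don <- exon_start + len
      if (don + 1L > L) next
      if (x[don] != "G" || x[don + 1L] != "T") next
      exon <- paste(x[exon_start:(exon_start + len - 1L)], collapse = "")
      hitfr <- NA_integer_; core <- NA_character_
      for (fr in 0:2) {
        aa <- translate_nt(exon, fr)
        if (!length(aa) || anyNA(aa)) next
        pep <- paste(aa, collapse = "")
        mm <- regexpr(config$core_pattern, pep)
        if (mm[1] != -1) {
          hitfr <- fr
          core <- substr(pep, mm[1], mm[1] + attr(mm, "match.length") - 1L)
          break
        }
      }
      if (is.na(hitfr)) next
      score <- (2L - h_mm) + (2L - best_n$mm) + as.integer(grepl("^FG.G$", core))
      exon_start0 <- exon_start - 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        exon_start = exon_start0, exon_end = exon_start0 + len,
        frame = hitfr, core_motif = core,
        heptamer_start = h - 1L,
        heptamer_seq = paste(hseq, collapse = ""),
        heptamer_mm = h_mm,
        spacer_length = best_n$spacer,
        nonamer_seq = best_n$seq, nonamer_mm = best_n$mm,
        splice_donor_pos = don - 1L,
        score = score
      )
      break
    }
  }
  dplyr::bind_rows(out)
}

#' Scan a genomic scaffold for candidate J segments
#'
#' Both strands are scanned; overlapping candidates are deduplicated
#' keeping the highest score, ties to the leftmost start. Coordinates are
#' 0-based half-open on the forward strand of the scaffold.
#'
#' @param scaffold Scaffold nucleotide string (>= 200 nt).
#' @param config [jscan_config()] object.
#' @param scaffold_id Scaffold name for the output.
#' @return Tibble of candidates: `scaffold_id`, `exon_start`, `exon_end`,
#'   `strand`, `frame`, `core_motif`, heptamer/spacer/nonamer fields,
#'   `splice_donor_pos`, `score`.
#' @export
scan_j_segments <- function(scaffold, config = jscan_config(),
                            scaffold_id = "scaffold") {
  if (!inherits(config, "shm_jscan_config")) stop_shm("invalid config")
  L <- nchar(scaffold)
  if (L < 200) stop_shm("scaffold must be >= 200 nt")
  fwd <- scan_j_one_strand(scaffold, config)
  if (nrow(fwd)) fwd$strand <- "+"
  rev <- scan_j_one_strand(revcomp(scaffold), config)
  if (nrow(rev)) {
    # mirror local minus-strand coordinates back to the forward strand
    flip <- function(start, end) c(L - end, L - start)
    mirrored <- purrr::map_dfr(seq_len(nrow(rev)), function(i) {
      e <- flip(rev$exon_start[i], rev$exon_end[i])
      d <- flip(rev$splice_donor_pos[i], rev$splice_donor_pos[i] + 2L)
      h <- flip(rev$heptamer_start[i], rev$heptamer_start[i] + nchar(config$heptamer))
      dplyr::mutate(rev[i, ], exon_start = e[1], exon_end = e[2],
                    splice_donor_pos = d[1], heptamer_start = h[1])
    })
    mirrored$strand <- "-"
    rev <- mirrored
  }
  cand <- dplyr::bind_rows(fwd, rev)
  if (nrow(cand) == 0) {
    return(tibble::tibble(scaffold_id = character(0), exon_start = integer(0),
                          exon_end = integer(0), strand = character(0),
                          frame = integer(0), core_motif = character(0),
                          heptamer_start = integer(0), heptamer_seq = character(0),
                          heptamer_mm = integer(0), spacer_length = integer(0),
                          nonamer_seq = character(0), nonamer_mm = integer(0),
                          splice_donor_pos = integer(0), score = integer(0)))
  }
  cand <- dplyr::arrange(cand, -.data$score, .data$exon_start)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i)
    ov <- later[cand$exon_start[later] < cand$exon_end[i] &
                  cand$exon_end[later] > cand$exon_start[i]]
    keep[ov] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- dplyr::arrange(cand, .data$exon_start)
  dplyr::bind_cols(tibble::tibble(scaffold_id = scaffold_id), cand) |>
    dplyr::select("scaffold_id", "exon_start", "exon_end", "strand", "frame",
                  "core_motif", "heptamer_start", "heptamer_seq",
                  "heptamer_mm", "spacer_length", "nonamer_seq", "nonamer_mm",
                  "splice_donor_pos", "score")
}

#' Build a J library from scan candidates
#'
#' Candidates are ordered 5' to 3' on the scaffold, duplicated coordinates
#' collapsed, and named `<prefix><index>`; minus-strand exons are
#' reverse-complemented so library sequences read in transcript
#' orientation. The result feeds [assign_j_segment()].
#'
#' @param candidates Candidate tibble from [scan_j_segments()].
#' @param scaffold The scaffold string the candidates were found on.
#' @param prefix Id prefix (default `"J"`).
#' @return Tibble `j_id`, `scaffold_id`, `exon_start`, `exon_end`,
#'   `strand`, `sequence`.
#' @export
build_j_library <- function(candidates, scaffold, prefix = "J") {
  if (nrow(candidates) == 0) {
    warning("empty candidate list: returning empty J library", call. = FALSE)
    return(tibble::tibble(j_id = character(0), scaffold_id = character(0),
                          exon_start = integer(0), exon_end = integer(0),
                          strand = character(0), sequence = character(0)))
  }
  cand <- candidates |>
    dplyr::distinct(.data$exon_start, .data$exon_end, .data$strand,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$exon_start)
  seqs <- substring(scaffold, cand$exon_start + 1L, cand$exon_end)
  seqs[cand$strand == "-"] <- revcomp(seqs[cand$strand == "-"])
  tibble::tibble(
    j_id = sprintf("%s%02d", prefix, seq_len(nrow(cand))),
    scaffold_id = cand$scaffold_id,
    exon_start = cand$exon_start, exon_end = cand$exon_end,
    strand = cand$strand, sequence = seqs
  )
}
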