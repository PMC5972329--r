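# AID hotspot (RGYW/WRCY) and polymerase-eta (WA/TW) motif scanning.
#
# Degenerate alphabet: R = A/G, Y = C/T, W = A/T. The mutable position is
# the G of RGYW, the C of WRCY, the A of WA and the T of TW (the WA/TW
# mutable-position semantics follow the AID-position rule by analogy).
# Scanning is on the given (sense) strand; the reverse complement of every
# RGYW window is a WRCY window on the other strand, so reverse-strand hits
# are available by scanning revcomp().

MOTIF_DEFS <- list(
  AID_RGYW = list(regex = "[AG]G[CT][AT]", len = 4L, offset = 1L, base = "G"),
  AID_WRCY = list(regex = "[AT][AG]C[CT]", len = 4L, offset = 2L, base = "C"),
  WA       = list(regex = "[AT]A",         len = 2L, offset = 1L, base = "A"),
  TW       = list(regex = "T[AT]",         len = 2L, offset = 0L, base = "T")
)

#' Scan a sequence for SHM-associated motifs
#'
#' All overlapping hits are reported (no greedy consumption); one position
#' may be the mutable position of several classes. Windows containing N
#' never match.
#'
#' @param sequence Nucleotide string over A,C,G,T,N.
#' @param classes Motif classes to scan, a subset of
#'   `c("AID_RGYW", "AID_WRCY", "WA", "TW")`.
#' @return Tibble `motif_class`, `window_start`, `window_end` (0-based
#'   half-open), `mutable_position`.
#' @export
scan_motifs <- function(sequence,
                        classes = c("AID_RGYW", "AID_WRCY", "WA", "TW")) {
  unknown <- setdiff(classes, names(MOTIF_DEFS))
  if (length(unknown)) stop_shm("unknown motif class: ",
                                paste(unknown, collapse = ", "))
  if (grepl("[^ACGTN]", sequence)) stop_shm("sequence restricted to A,C,G,T,N")
  purrr::map_dfr(classes, function(cl) {
    def <- MOTIF_DEFS[[cl]]
    m <- gregexpr(paste0("(?=", def$regex, ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1) {
      return(tibble::tibble(motif_class = character(0),
                            window_start = integer(0),
                            window_end = integer(0),
                            mutable_position = integer(0)))
    }
    start0 <- as.integer(m) - 1L
    tibble::tibble(
      motif_class = cl,
      window_start = start0,
      window_end = start0 + def$len,
      mutable_position = start0 + def$offset
    )
  })
}

#' Motif density per 100 bp
#'
#' Hits whose window is fully unmasked, per 100 unmasked bases.
#'
#' @param sequence Nucleotide string.
#' @param classes Motif classes (each reported separately).
#' @param masked_spans Optional masked spans tibble.
#' @return Tibble `motif_class`, `n_hits`, `density_per_100bp`.
#' @export
motif_density <- function(sequence,
                          classes = c("AID_RGYW", "AID_WRCY", "WA", "TW"),
                          masked_spans = NULL) {
  L <- nchar(sequence)
  if (L == 0) stop_shm("zero-length sequence")
  mask <- mask_vector(L, masked_spans)
  unmasked <- sum(!mask)
  if (unmasked == 0) stop_shm("sequence fully masked")
  hits <- scan_motifs(sequence, classes)
  keep <- vapply(seq_len(nrow(hits)), function(i) {
    !any(mask[(hits$window_start[i] + 1L):hits$window_end[i]])
  }, logical(1))
  hits <- hits[keep, , drop = FALSE]
  purrr::map_dfr(classes, function(cl) {
    n <- sum(hits$motif_class == cl)
    tibble::tibble(motif_class = cl, n_hits = n,
                   density_per_100bp = 100 * n / unmasked)
  })
}

#' Fraction of mutations at motif-mutable positions
#'
#' A substitution counts for a class when its reference position equals a
#' hit's mutable position of that class and its germline base matches the
#' class's mutable base. Substitutions inside a motif window but not at the
#' mutable position are tallied separately as in-window, non-mutable.
#' Fractions are over substitution records only.
#'
#' @param records Mutation-record tibble.
#' @param hits Motif-hit tibble from [scan_motifs()] on the same reference.
#' @return Tibble `motif_class`, `n_substitutions`, `n_at_mutable`,
#'   `fraction`, `n_in_window_non_mutable`.
#' @export
motif_overlap <- function(records, hits) {
  subs <- records[records$event_class == "substitution", , drop = FALSE]
  n_subs <- nrow(subs)
  classes <- unique(hits$motif_class)
  purrr::map_dfr(classes, function(cl) {
    h <- hits[hits$motif_class == cl, , drop = FALSE]
    base <- MOTIF_DEFS[[cl]]$base
    at_mutable <- subs$position %in% h$mutable_position & subs$from_base == base
    in_window <- vapply(subs$position, function(p) {
      any(p >= h$window_start & p < h$window_end)
    }, logical(1))
    tibble::tibble(
      motif_class = cl,
      n_substitutions = n_subs,
      n_at_mutable = sum(at_mutable),
      fraction = if (n_subs > 0) sum(at_mutable) / n_subs else 0,
      n_in_window_non_mutable = sum(in_window & !at_mutable)
    )
  })
}

#' Annotate mutation records with motif flags
#'
#' Adds a `motif_flags` column: comma-joined classes (over AID, WA, TW
#' groupings) whose mutable position coincides with the record's position
#' and base.
#'
#' @param records Mutation-record tibble.
#' @param hits Motif-hit tibble on the same reference.
#' @return `records` with a `motif_flags` character column ("" when none).
#' @export
annotate_motif_flags <- function(records, hits) {
  flag_group <- c(AID_RGYW = "AID", AID_WRCY = "AID", WA = "WA", TW = "TW")
  flags <- vapply(seq_len(nrow(records)), function(i) {
    if (records$event_class[i] != "substitution") return("")
    sel <- hits$mutable_position == records$position[i] &
      vapply(hits$motif_class, function(cl) MOTIF_DEFS[[cl]]$base,
             character(1)) == records$from_base[i]
    paste(sort(unique(flag_group[hits$motif_class[sel]])), collapse = ",")
  }, character(1))
  dplyr::mutate(records, motif_flags = flags)
}
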