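# Pairwise clone-versus-reference alignment.
#
# Scoring: match +1, mismatch -1, a gap of length L costs 4 + (L - 1),
# terminal gaps free (ends-free / overlap alignment). Near-identical clones
# make the result insensitive to these constants; they are fixed for
# determinism. Backed by Biostrings::pairwiseAlignment.

shm_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

#' Align a clone to a reference sequence
#'
#' Ends-free global alignment with fixed scoring (match +1, mismatch -1,
#' gap open -4, gap extend -1, terminal gaps free). Returns per-column pairs
#' and substitution / indel events in reference coordinates (0-based).
#' Columns where either sequence carries `N` are reported in the column map
#' but never produce events and are excluded from the surveyed-base count.
#'
#' @param clone_seq Clone nucleotide string.
#' @param ref_seq Reference nucleotide string.
#' @return List with elements `score`, `events` (tibble: `event_class`,
#'   `ref_start`, `ref_end`, `from_base`, `to_base`, `length`), `columns`
#'   (tibble: `ref_pos`, `clone_pos`, `ref_base`, `clone_base`),
#'   `ref_span` (0-based half-open aligned span on the reference) and
#'   `surveyed_bp` (aligned, non-gap, non-N columns).
#' @export
align_clone <- function(clone_seq, ref_seq) {
  if (!nzchar(clone_seq) || !nzchar(ref_seq)) stop_shm("empty sequence")
  if (nchar(clone_seq) == nchar(ref_seq)) {
    # identical-length near-identical sequences: scattered substitutions
    # cannot be outscored by any gapped alignment (an insertion-deletion
    # pair costs at least 8 and only pays against a shifted run of
    # mismatches), so up to ~10% divergence the identity alignment is the
    # optimum and the DP is skipped
    a <- seq_chars(clone_seq); b <- seq_chars(ref_seq)
    mism <- sum(a != b & a != "N" & b != "N")
    if (mism <= 0.1 * length(a)) {
      return(alignment_from_strings(a, b, ref0 = 0L, clone0 = 0L,
                                    score = sum(a == b) - mism))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(clone_seq),
    subject = Biostrings::DNAString(ref_seq),
    type = "overlap", substitutionMatrix = shm_submat(),
    gapOpening = 3, gapExtension = 1
  )
  ap <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  as_ <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  alignment_from_strings(
    ap, as_,
    ref0 = BiocGenerics::start(Biostrings::subject(pa)) - 1L,
    clone0 = BiocGenerics::start(Biostrings::pattern(pa)) - 1L,
    score = Biostrings::score(pa)
  )
}

# build the column map and event list from two equal-length aligned
# character vectors (clone row `ap`, reference row `as_`)
alignment_from_strings <- function(ap, as_, ref0, clone0, score) {
  ref_gap <- as_ == "-"
  clone_gap <- ap == "-"
  ref_pos <- ref0 + cumsum(!ref_gap) - 1L
  ref_pos[ref_gap] <- NA_integer_
  clone_pos <- clone0 + cumsum(!clone_gap) - 1L
  clone_pos[clone_gap] <- NA_integer_

  columns <- tibble::new_tibble(
    list(ref_pos = ref_pos, clone_pos = clone_pos,
         ref_base = as_, clone_base = ap),
    nrow = length(ap))

  is_n <- ap == "N" | as_ == "N"
  subs <- which(!ref_gap & !clone_gap & ap != as_ & !is_n)
  ev_sub <- tibble::new_tibble(
    list(event_class = rep("substitution", length(subs)),
         ref_start = ref_pos[subs],
         ref_end = ref_pos[subs] + 1L,
         from_base = as_[subs],
         to_base = ap[subs],
         length = rep(1L, length(subs))),
    nrow = length(subs))

  gap_events <- function(gap, class) {
    if (!any(gap)) return(NULL)
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    purrr::map_dfr(keep, function(i) {
      cols <- starts[i]:ends[i]
      if (class == "deletion") {
        tibble::tibble(
          event_class = "deletion",
          ref_start = ref_pos[cols[1]],
          ref_end = ref_pos[cols[length(cols)]] + 1L,
          from_base = paste(as_[cols], collapse = ""),
          to_base = "",
          length = length(cols)
        )
      } else {
        # insertion: anchored at the next reference position
        nxt <- ref_pos[seq(cols[length(cols)] + 1L, length(ref_pos))]
        anchor <- if (length(nxt)) nxt[!is.na(nxt)][1] else NA_integer_
        tibble::tibble(
          event_class = "insertion",
          ref_start = anchor, ref_end = anchor,
          from_base = "",
          to_base = paste(ap[cols], collapse = ""),
          length = length(cols)
        )
      }
    })
  }

  events <- dplyr::bind_rows(
    ev_sub,
    gap_events(clone_gap, "deletion"),
    gap_events(ref_gap, "insertion")
  )
  if (nrow(events)) events <- dplyr::arrange(events, .data$ref_start)

  aligned_ref <- ref_pos[!is.na(ref_pos)]
  list(
    score = score,
    events = events,
    columns = columns,
    ref_span = c(start = aligned_ref[1], end = aligned_ref[length(aligned_ref)] + 1L),
    surveyed_bp = sum(!ref_gap & !clone_gap & !is_n)
  )
}
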