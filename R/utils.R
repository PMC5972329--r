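#' @keywords internal
#' @importFrom rlang .data
#' @importFrom tibble tibble
#' @importFrom dplyr %>%
"_PACKAGE"

# All coordinates in this package are 0-based half-open unless a column name
# carries the suffix `_1based`.

VALID_REGION_NAMES <- c(
  "FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4",
  "C-Ig", "C-CP", "C-TM", "C-CYT"
)

DNA_BASES <- c("A", "C", "G", "T")

#' Truncate a number toward zero at a fixed number of decimals
#'
#' Report tables print ratios truncated (not rounded) toward zero, e.g. a
#' replacement/synonymous ratio of 26/14 = 1.857 prints as 1.85. Full
#' precision is always retained in returned tibbles; this helper only
#' formats.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals to keep.
#' @return Numeric vector truncated toward zero.
#' @export
#' @examples
#' printed_value(26 / 14, 2) # 1.85
printed_value <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Reverse-complement a nucleotide string
#'
#' @param x Character vector of sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# logical mask of length `len`: TRUE where position is inside a masked span.
# `spans` is a data frame with columns start/end (0-based half-open) or NULL.
mask_vector <- function(len, spans = NULL) {
  m <- logical(len)
  if (is.null(spans) || nrow(spans) == 0) return(m)
  for (i in seq_len(nrow(spans))) {
    lo <- max(0L, spans$start[i])
    hi <- min(len, spans$end[i])
    if (hi > lo) m[(lo + 1):hi] <- TRUE
  }
  m
}

# translate an in-frame nucleotide string to amino acids; codons containing
# non-ACGT characters translate to NA, partial trailing codon dropped
translate_nt <- function(s, frame = 0) {
  s <- substr(s, frame + 1, nchar(s))
  n <- nchar(s) %/% 3
  if (n == 0) return(character(0))
  starts <- seq(1, by = 3, length.out = n)
  codons <- substring(s, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa
}

is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

stop_shm <- function(...) stop(..., call. = FALSE)

check_clone_tbl <- function(clones) {
  if (!is.data.frame(clones) || !all(c("clone_id", "sequence") %in% names(clones))) {
    stop_shm("`clones` must be a data frame with columns clone_id and sequence")
  }
  if (nrow(clones) == 0) stop_shm("empty clone set")
  if (anyDuplicated(clones$clone_id)) {
    stop_shm("clone_id values must be unique within a dataset")
  }
  bad <- grepl("[^ACGTN]", clones$sequence)
  if (any(bad)) {
    stop_shm("sequences restricted to A,C,G,T,N; offending clone(s): ",
             paste(clones$clone_id[bad], collapse = ", "))
  }
  invisible(clones)
}

# drop the package's S3 class tag from a tibble (for row-binding)
strip_cls <- function(x, cls = c("shm_summary", "shm_mi")) {
  class(x) <- setdiff(class(x), cls)
  x
}
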