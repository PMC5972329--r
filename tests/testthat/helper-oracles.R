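# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check.

# uniform random DNA string
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# brute-force sliding-window motif scan: explicit per-position base-set
# checks, no regular expressions
oracle_scan_motifs <- function(sequence) {
  x <- strsplit(sequence, "")[[1]]
  L <- length(x)
  R <- c("A", "G"); Y <- c("C", "T"); W <- c("A", "T")
  out <- list()
  add <- function(cl, s, len, off) {
    out[[length(out) + 1L]] <<- data.frame(
      motif_class = cl, window_start = s - 1L, window_end = s - 1L + len,
      mutable_position = s - 1L + off, stringsAsFactors = FALSE)
  }
  for (s in seq_len(L)) {
    if (s + 3 <= L) {
      w <- x[s:(s + 3)]
      if (w[1] %in% R && w[2] == "G" && w[3] %in% Y && w[4] %in% W)
        add("AID_RGYW", s, 4L, 1L)
      if (w[1] %in% W && w[2] %in% R && w[3] == "C" && w[4] %in% Y)
        add("AID_WRCY", s, 4L, 2L)
    }
    if (s + 1 <= L) {
      w <- x[s:(s + 1)]
      if (w[1] %in% W && w[2] == "A") add("WA", s, 2L, 1L)
      if (w[1] == "T" && w[2] %in% W) add("TW", s, 2L, 0L)
    }
  }
  if (!length(out)) {
    return(data.frame(motif_class = character(0), window_start = integer(0),
                      window_end = integer(0), mutable_position = integer(0)))
  }
  do.call(rbind, out)
}

# R/S oracle: classify a single substitution by translating the FULL
# mutant sequence and comparing whole protein sequences
oracle_effect <- function(ref, pos0, to) {
  mut <- ref
  substr(mut, pos0 + 1, pos0 + 1) <- to
  tr <- function(s) {
    n <- nchar(s) %/% 3
    starts <- seq(1, by = 3, length.out = n)
    unname(Biostrings::GENETIC_CODE[substring(s, starts, starts + 2)])
  }
  a <- tr(ref); b <- tr(mut)
  if (identical(a, b)) return("synonymous")
  changed <- which(a != b)
  if (any(b[changed] == "*")) return("nonsense")
  "replacement"
}

# neutral R/S expectation by exhaustive enumeration of every single-base
# change in a reference (composition-dependent, not an assumed constant)
oracle_neutral_rs <- function(ref) {
  counts <- c(replacement = 0, synonymous = 0, nonsense = 0)
  x <- strsplit(ref, "")[[1]]
  for (p in seq_along(x)) {
    for (b in setdiff(c("A", "C", "G", "T"), x[p])) {
      e <- oracle_effect(ref, p - 1L, b)
      counts[e] <- counts[e] + 1
    }
  }
  counts
}

# fixture builder: mutation-record tibble realizing given event-class
# counts (used for report-shaped summaries); bases chosen so titv and
# effect are mutually consistent with real substitution chemistry
make_record_fixture <- function(n_repl_ti, n_repl_tv, n_silent_ti,
                                n_silent_tv, n_frameshift = 0,
                                clone_id = "fx") {
  mk <- function(n, from, to, titv, effect) {
    if (n == 0) return(NULL)
    tibble::tibble(
      clone_id = clone_id, position = seq_len(n) - 1L,
      from_base = from, to_base = to, event_class = "substitution",
      length = 1L, titv = titv, effect = effect, region = NA_character_)
  }
  fs <- if (n_frameshift > 0) tibble::tibble(
    clone_id = clone_id, position = seq_len(n_frameshift) - 1L,
    from_base = "A", to_base = "", event_class = "deletion",
    length = 1L, titv = "n/a", effect = "frameshift",
    region = NA_character_) else NULL
  empty <- tibble::tibble(
    clone_id = character(0), position = integer(0), from_base = character(0),
    to_base = character(0), event_class = character(0), length = integer(0),
    titv = character(0), effect = character(0), region = character(0))
  dplyr::bind_rows(
    empty,
    mk(n_repl_ti, "A", "G", "transition", "replacement"),
    mk(n_repl_tv, "A", "C", "transversion", "replacement"),
    mk(n_silent_ti, "C", "T", "transition", "synonymous"),
    mk(n_silent_tv, "G", "T", "transversion", "synonymous"),
    fs)
}

# build a J cassette that satisfies every scanner rule exactly:
# nonamer + spacer + heptamer + exon (FGSG core in frame 0) + GT donor
make_j_cassette <- function(exon_codons = 16, spacer = 12) {
  core <- "TTTGGATCAGGA"  # F G S G
  n_extra <- exon_codons - 4
  n_before <- n_extra %/% 2
  safe_codons <- c("GCT", "ACT", "CTT", "GAT")  # no stops, no FGXG
  exon <- paste0(
    paste(sample(safe_codons, n_before, replace = TRUE), collapse = ""),
    core,
    paste(sample(safe_codons, n_extra - n_before, replace = TRUE),
          collapse = ""))
  spacer_seq <- random_dna(spacer)
  list(
    cassette = paste0("ACAAAAACC", spacer_seq, "CACAGTG", exon, "GT"),
    exon = exon,
    exon_offset = 9 + spacer + 7   # exon start within the cassette
  )
}
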