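# Mutability index: observed versus composition-expected mutation counts
# per mono-, di- and trinucleotide, with per-k-mer chi-square significance.
#
# Attribution convention (the source data never fix one): a substitution at
# reference position i is attributed, for k = 1, to the germline base at i;
# for k = 2, to the dinucleotide starting at i (falling back to (i-1, i) at
# the last position); for k = 3, to the trinucleotide centered on i, with
# edge positions excluded. This single-attribution rule keeps
# sum(observed) = total and makes observed and expected comparable. An
# alternative "both" rule counts a mutated base into both overlapping
# dinucleotides (with correspondingly doubled total).

#' Relative k-mer composition of a reference
#'
#' Overlapping k-mer counts over unmasked positions, normalized to
#' frequencies summing to 1. For k > 1 a window is counted only when fully
#' unmasked and N-free.
#'
#' @param reference Reference nucleotide string.
#' @param k K-mer size (1, 2 or 3).
#' @param masked_spans Optional masked spans tibble (`start`, `end`).
#' @return Tibble `kmer`, `count`, `freq` over all 4^k k-mers.
#' @export
kmer_composition <- function(reference, k, masked_spans = NULL) {
  stopifnot(k %in% 1:3)
  L <- nchar(reference)
  if (L < k) stop_shm("reference shorter than k")
  mask <- mask_vector(L, masked_spans)
  chars <- seq_chars(reference)
  starts <- seq_len(L - k + 1L)
  ok <- vapply(starts, function(s) {
    win <- s:(s + k - 1L)
    !any(mask[win]) && all(chars[win] %in% DNA_BASES)
  }, logical(1))
  if (!any(ok)) stop_shm("reference fully masked")
  kmers <- substring(reference, starts[ok], starts[ok] + k - 1L)
  all_kmers <- apply(expand.grid(rep(list(DNA_BASES), k))[, k:1, drop = FALSE],
                     1, paste, collapse = "")
  counts <- table(factor(kmers, levels = all_kmers))
  tibble::tibble(
    kmer = all_kmers,
    count = as.integer(counts),
    freq = as.integer(counts) / sum(counts)
  )
}

#' Expected mutation counts from composition
#'
#' expected(kmer) = freq(kmer) x total observed mutations, so the expected
#' counts conserve the observed total.
#'
#' @param composition Tibble from [kmer_composition()] (columns `kmer`,
#'   `freq`).
#' @param total_observed Total observed mutation attributions.
#' @return Tibble `kmer`, `expected`.
#' @export
expected_mutations <- function(composition, total_observed) {
  if (total_observed < 0) stop_shm("total_observed must be >= 0")
  tibble::tibble(kmer = composition$kmer,
                 expected = composition$freq * total_observed)
}

#' Mutability index
#'
#' observed / expected; 1 means unbiased targeting. With expected 0 the
#' index is NA (and flagged unattributable when observed > 0).
#'
#' @param observed,expected Numeric vectors.
#' @return Numeric vector of MI values.
#' @export
mutability_index <- function(observed, expected) {
  mi <- ifelse(expected > 0, observed / expected, NA_real_)
  bad <- expected == 0 & observed > 0
  if (any(bad, na.rm = TRUE)) {
    warning("unattributable: observed > 0 with expected = 0", call. = FALSE)
  }
  mi
}

#' Attribute substitution records to k-mers
#'
#' Indels and masked-span events are excluded; see the attribution
#' convention at the top of this file.
#'
#' @param records Mutation-record tibble (substitutions are selected
#'   internally).
#' @param reference Germline reference string.
#' @param k K-mer size (1, 2 or 3).
#' @param masked_spans Optional masked spans tibble.
#' @param rule `"start"` (single attribution, default) or `"both"`
#'   (dinucleotides only: each event attributed to both overlapping
#'   windows).
#' @return Tibble `kmer`, `observed` over all 4^k k-mers.
#' @export
attribute_mutations <- function(records, reference, k, masked_spans = NULL,
                                rule = c("start", "both")) {
  stopifnot(k %in% 1:3)
  rule <- match.arg(rule)
  L <- nchar(reference)
  mask <- mask_vector(L, masked_spans)
  subs <- records[records$event_class == "substitution", , drop = FALSE]
  if (nrow(subs) && (min(subs$position) < 0 || max(subs$position) >= L)) {
    stop_shm("record position outside reference")
  }
  pos <- subs$position[!mask[subs$position + 1L]]
  kmer_at <- function(p) {   # p 0-based
    if (k == 1) return(substr(reference, p + 1, p + 1))
    if (k == 2) {
      s <- if (p == L - 1L) p - 1L else p
      return(substr(reference, s + 1, s + 2))
    }
    if (p == 0L || p == L - 1L) return(NA_character_)
    substr(reference, p, p + 2)
  }
  kmers <- vapply(pos, kmer_at, character(1))
  if (rule == "both" && k == 2) {
    extra <- vapply(pos, function(p) {
      if (p == 0L || p == L - 1L) NA_character_ else substr(reference, p, p + 1)
    }, character(1))
    kmers <- c(kmers, extra)
  }
  kmers <- kmers[!is.na(kmers) & !grepl("N", kmers)]
  all_kmers <- apply(expand.grid(rep(list(DNA_BASES), k))[, k:1, drop = FALSE],
                     1, paste, collapse = "")
  counts <- table(factor(kmers, levels = all_kmers))
  tibble::tibble(kmer = all_kmers, observed = as.integer(counts))
}

#' Per-k-mer chi-square test of the mutability index
#'
#' Two-cell goodness-of-fit per k-mer (df = 1):
#' chi2 = (obs - exp)^2 / exp + ((total - obs) - (total - exp))^2 /
#' (total - exp), with the p-value from the chi-square survival function.
#' Degenerate cells (expected 0 or expected = total) return NA.
#'
#' @param observed,expected Numeric vectors (recycled against each other).
#' @param total_observed Total observed attributions.
#' @return Tibble `chi2`, `p_value`.
#' @export
chi_square_mi <- function(observed, expected, total_observed) {
  if (any(observed > total_observed)) {
    stop_shm("observed exceeds total_observed")
  }
  ok <- expected > 0 & expected < total_observed
  chi2 <- rep(NA_real_, length(observed))
  d <- observed - expected
  chi2[ok] <- d[ok]^2 / expected[ok] + d[ok]^2 / (total_observed - expected[ok])
  p <- ifelse(is.na(chi2), NA_real_,
              stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  tibble::tibble(chi2 = chi2, p_value = p)
}

#' Full mutability table for one k
#'
#' Composition, expected counts, MI and chi-square significance in one
#' tibble — the shape of the mono/di/trinucleotide report tables. No
#' multiple-testing correction is applied (the number of tests equals the
#' number of k-mers and is recorded as an attribute).
#'
#' @param records Mutation-record tibble.
#' @param reference Germline reference string.
#' @param k K-mer size (1, 2 or 3).
#' @param masked_spans Optional masked spans tibble.
#' @param rule Attribution rule, see [attribute_mutations()].
#' @return Tibble of class `shm_mi`: `kmer`, `observed`, `expected`, `mi`,
#'   `chi2`, `p_value`, `sig_0.01`, `sig_0.001`.
#' @export
mutability_table <- function(records, reference, k, masked_spans = NULL,
                             rule = "start") {
  obs <- attribute_mutations(records, reference, k, masked_spans, rule = rule)
  comp <- kmer_composition(reference, k, masked_spans)
  total <- sum(obs$observed)
  out <- comp |>
    dplyr::inner_join(obs, by = "kmer") |>
    dplyr::mutate(expected = .data$freq * total,
                  mi = mutability_index(.data$observed, .data$expected))
  chi <- chi_square_mi(out$observed, out$expected, total)
  out <- dplyr::bind_cols(out, chi) |>
    dplyr::mutate(
      sig_0.01 = !is.na(.data$p_value) & .data$p_value < 0.01,
      sig_0.001 = !is.na(.data$p_value) & .data$p_value < 0.001
    ) |>
    dplyr::select("kmer", "observed", "expected", "mi", "chi2", "p_value",
                  "sig_0.01", "sig_0.001")
  # drop k-mers absent from both the reference and the observations
  out <- out[!(out$expected == 0 & out$observed == 0), , drop = FALSE]
  attr(out, "k") <- k
  attr(out, "total_observed") <- total
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  class(out) <- c("shm_mi", class(out))
  out
}
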