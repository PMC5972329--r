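# Tidiers and plots for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutability table
#'
#' @param x `shm_mi` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @exportS3Method generics::tidy
tidy.shm_mi <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "shm_mi")
  tibble::as_tibble(out)
}

#' One-row summary of a mutability table
#'
#' @param x `shm_mi` object.
#' @param ... Unused.
#' @return Tibble with k, totals and significance counts.
#' @exportS3Method generics::glance
glance.shm_mi <- function(x, ...) {
  tibble::tibble(
    k = attr(x, "k"),
    total_observed = attr(x, "total_observed"),
    n_kmers = nrow(x),
    n_tests = attr(x, "n_tests"),
    n_sig_0.01 = sum(x$sig_0.01),
    n_sig_0.001 = sum(x$sig_0.001),
    max_mi = max(x$mi, na.rm = TRUE),
    min_mi = min(x$mi[x$expected > 0], na.rm = TRUE)
  )
}

#' Tidy a mutation summary
#'
#' @param x `shm_summary` object.
#' @param ... Unused.
#' @return The underlying tibble.
#' @exportS3Method generics::tidy
tidy.shm_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "shm_summary")
  tibble::as_tibble(out)
}

#' One-row overview of a mutation summary
#'
#' @param x `shm_summary` object.
#' @param ... Unused.
#' @return Tibble with the headline rate and ratios (full precision).
#' @exportS3Method generics::glance
glance.shm_summary <- function(x, ...) {
  tot <- x[nrow(x), ]
  tibble::tibble(
    n_clones = tot$n_clones, n_bp = tot$n_bp, n_events = tot$n_events,
    freq_per_kb = tot$freq_per_kb, rs_ratio = tot$rs_ratio,
    titv_ratio = tot$titv_ratio
  )
}

#' Plot a mutability table
#'
#' Bar chart of MI per k-mer with the unbiased level (MI = 1) marked and
#' chi-square significance indicated by fill.
#'
#' @param object `shm_mi` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.shm_mi <- function(object, ...) {
  d <- tidy(object)
  d$significance <- ifelse(d$sig_0.001, "p < 0.001",
                           ifelse(d$sig_0.01, "p < 0.01", "n.s."))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$kmer, -.data$mi),
                                  y = .data$mi,
                                  fill = .data$significance)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "k-mer", y = "mutability index (observed/expected)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a per-window mutation frequency profile
#'
#' Line track of per-site substitution frequency per window and effect
#' class, the shape used to localize hotspots along the receptor.
#'
#' @param windows Tibble from [window_profile()].
#' @param rmap Optional region map drawn as background strips.
#' @return A ggplot object.
#' @export
plot_window_profile <- function(windows, rmap = NULL) {
  p <- ggplot2::ggplot(windows,
                       ggplot2::aes(x = .data$window_start,
                                    y = .data$frequency,
                                    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (bp)", y = "mutations per site per clone",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(rmap)) {
    p <- p + ggplot2::geom_vline(xintercept = rmap$regions$start,
                                 linetype = "dotted", colour = "grey70")
  }
  p
}
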