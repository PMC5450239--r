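# ggplot2 views of fits and frequency comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an EM fit
#'
#' `type = "trace"` shows the observed-data log-likelihood across EM
#' iterations (monotone by construction); `type = "spectrum"` shows the
#' estimated frequencies against their rank on log scales.
#'
#' @param object An `hla_em_fit`.
#' @param type `"trace"` or `"spectrum"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hla_em_fit
#' @export
autoplot.hla_em_fit <- function(object, type = c("trace", "spectrum"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble(iteration = seq_along(object$trace),
      log_likelihood = object$trace)
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "EM iteration", y = "log-likelihood",
        title = "EM log-likelihood trace") +
      ggplot2::theme_minimal()
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$frequency)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "haplotype rank", y = "estimated frequency",
        title = "Haplotype frequency spectrum") +
      ggplot2::theme_minimal()
  }
}

#' Estimated versus reference haplotype frequencies
#'
#' Log-log scatter of estimated against reference frequencies on the shared
#' support (additional and missing haplotypes have a zero on one axis and
#' cannot be drawn on log scales; their counts are given in the subtitle).
#'
#' @param estimate,reference Frequency tibbles, named vectors or fits.
#' @return A ggplot object.
#' @export
plot_frequency_comparison <- function(estimate, reference) {
  est <- as_freq_tbl(estimate, "estimate")
  ref <- as_freq_tbl(reference, "reference")
  cmp <- compare_frequency_sets(est, ref)
  df <- dplyr::inner_join(
    dplyr::rename(est, estimated = "frequency"),
    dplyr::rename(ref, reference = "frequency"),
    by = "haplotype"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "reference frequency", y = "estimated frequency",
      title = "Haplotype frequency comparison",
      subtitle = sprintf("d = %.3g, Δ = %.3g, %d additional / %d missing",
        cmp$d, cmp$delta, cmp$n_additional, cmp$n_missing)
    ) +
    ggplot2::theme_minimal()
}
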