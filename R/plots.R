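#' Plot an ideal coverage curve
#'
#' @param object A `coverage_curve` from [ideal_coverage_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.coverage_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycles, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = "Experimental cycles",
      y = "Proteins uniquely identified",
      title = sprintf("Ideal-condition coverage (%s anchor, scheme %s)",
                      attr(object, "anchor"), attr(object, "scheme"))
    )
}

#' Plot a labelable-count or length histogram
#'
#' @param object A `fluorosim_stats` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fluorosim_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$value, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$median, linetype = "dashed") +
    ggplot2::labs(x = object$what, y = "Peptides",
                  title = sprintf("%s (median %d, n = %d peptides)",
                                  object$what, object$median, object$n_peptides))
}

#' Plot an attribution probability mass function
#'
#' Bar chart of the empirical posterior over source proteins for one
#' observed fluorosequence, mirroring the two qualitative extremes of
#' attribution: one dominant source versus many rivals.
#'
#' @param object An `attribution_pmf` from [pmf_at()].
#' @param max_proteins Show at most this many top proteins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.attribution_pmf <- function(object, max_proteins = 20L, ...) {
  df <- head(object, max_proteins)
  df$protein_id <- factor(df$protein_id, levels = df$protein_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein_id, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Source protein", y = "P(protein | read)",
                  title = sprintf("Attribution p.m.f. for %s (n = %d)",
                                  attr(object, "fs"), attr(object, "total"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a parameter-sweep result
#'
#' Coverage against photobleaching half-life, one line per Edman efficiency,
#' faceted by dye-failure rate (infinite half-lives are drawn at the largest
#' finite value swept, marked on the axis).
#'
#' @param object A `sweep_result` from [parameter_sweep()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- as_tibble(object)
  finite_max <- max(df$half_life_cycles[is.finite(df$half_life_cycles)],
                    na.rm = TRUE)
  df$hl <- ifelse(is.finite(df$half_life_cycles), df$half_life_cycles,
                  finite_max * 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hl, y = .data$coverage,
                                   colour = factor(.data$edman_efficiency))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ dye_failure, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Photobleach half-life (cycles; rightmost = none)",
                  y = "Proteome coverage", colour = "Edman efficiency")
}
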