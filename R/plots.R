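#' Woods plot of differential exchange
#'
#' Draws each peptide as a horizontal segment spanning its residues at its
#' delta percent exchange, colored by labeling time, with the symmetric
#' global confidence limits as dashed lines. Peptides outside the limits are
#' the stabilized/destabilized calls.
#'
#' @param object An `hdx_differential`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hdx_differential
#' @export
autoplot.hdx_differential <- function(object, ...) {
  cl <- attr(object, "cl_pct")
  st <- attr(object, "states")
  df <- as_tibble(object) |>
    mutate(exposure = factor(.data$exposure_s,
                             labels = paste0(sort(unique(.data$exposure_s)), " s")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$delta_pct, yend = .data$delta_pct,
                                   color = .data$exposure)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_hline(yintercept = c(-cl, cl), linetype = "dashed") +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::labs(
      x = "Residue",
      y = sprintf("Δ%%EX (%s − %s)", st[["a"]], st[["b"]]),
      color = "Labeling time",
      title = "Differential deuterium exchange",
      subtitle = sprintf("Global 98%% confidence limit ±%.2f%%", cl)) +
    ggplot2::theme_minimal()
}

#' @method autoplot hdx_pipeline
#' @export
autoplot.hdx_pipeline <- function(object, ...) {
  autoplot.hdx_differential(object$differential, ...)
}

#' Uptake curves for selected peptides
#'
#' Mean percent exchange against labeling time (log axis) per state, with
#' error bars at one replicate SD — the per-peptide view behind a region
#' call.
#'
#' @param summaries Output of [aggregate_replicates()].
#' @param peptides Optional tibble (or data frame) with `start`, `end` rows
#'   selecting which peptides to draw; default all.
#' @return A ggplot object.
#' @export
plot_uptake_curves <- function(summaries, peptides = NULL) {
  df <- as_tibble(summaries)
  if (!is.null(peptides)) {
    df <- dplyr::semi_join(df, as_tibble(peptides), by = c("start", "end"))
  }
  df <- mutate(df, peptide = sprintf("%d–%d", .data$start, .data$end))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure_s, y = .data$mean_pct_ex,
                                   color = .data$state, group = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_pct_ex - .data$sd_pct_ex,
      ymax = .data$mean_pct_ex + .data$sd_pct_ex), width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~peptide) +
    ggplot2::labs(x = "Labeling time (s)", y = "%EX", color = "State") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
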