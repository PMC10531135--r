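# ggplot2 figure helpers for the usual fidelity plots.

#' Plot read-length distributions
#'
#' Overlaid density-style histograms of read length, optionally comparing
#' several datasets (e.g. real vs simulated), annotated with mean and SD.
#'
#' @param reads A read tibble, or a named list of read tibbles to overlay.
#' @param binwidth Histogram bin width in bases (default 20).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(reads, binwidth = 20) {
  if (is.data.frame(reads)) reads <- list(reads = reads)
  df <- purrr::imap_dfr(reads, function(r, nm)
    tibble(dataset = nm, length = nchar(r$sequence)))
  labs <- df |>
    group_by(.data$dataset) |>
    summarise(label = sprintf("%s: mean %.0f bp, SD %.0f bp",
                              .data$dataset[1L], mean(.data$length),
                              sqrt(mean((.data$length - mean(.data$length))^2))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$dataset)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.55,
                            position = "identity") +
    ggplot2::labs(x = "read length (bp)", y = "reads",
                  subtitle = paste(labs$label, collapse = "; ")) +
    ggplot2::theme_minimal()
}

#' Plot an identity histogram
#'
#' @param hist An [identity_histogram()] tibble.
#' @param min_identity Lower x-axis limit (default 60%).
#' @return A ggplot object.
#' @export
plot_identity_histogram <- function(hist, min_identity = 60) {
  ggplot2::ggplot(dplyr::filter(hist, .data$mid >= min_identity),
                  ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = hist$upper[1L] - hist$lower[1L]) +
    ggplot2::labs(x = "identity (%)", y = "reads") +
    ggplot2::theme_minimal()
}

#' Plot a fitted error-rate distribution
#'
#' Empirical error-rate histogram (reconstructed from the data the model was
#' fitted to is not retained, so supply a sample) with the fitted
#' exponentiated Weibull density overlaid.
#'
#' @param object An `exp_weibull_fit`.
#' @param sample Optional numeric vector of observed error-rate percentages
#'   to show behind the fitted density.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_weibull_fit <- function(object, sample = NULL, ...) {
  lo <- object$params$loc
  hi <- max(qexpweibull(0.999, object$params), lo + 1)
  grid <- tibble(x = seq(lo, hi, length.out = 400L))
  grid$density <- dexpweibull(grid$x, object$params)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density))
  if (!is.null(sample))
    p <- p + ggplot2::geom_histogram(
      data = tibble(s = sample),
      ggplot2::aes(x = .data$s, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 60, alpha = 0.4)
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "per-read error rate (%)", y = "density") +
    ggplot2::theme_minimal()
}
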