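#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-metric performance against the average-activity baseline
#' @param object A `metric_report` from [evaluate_compendium()].
#' @param ... Unused.
#' @return A ggplot: paired bars of mean model and baseline error per
#'   metric (when baseline columns are present), else model bars alone.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  summ <- tidy(object)
  if ("baseline" %in% names(summ)) {
    df <- tidyr::pivot_longer(summ[, c("metric", "model", "baseline")],
                              c("model", "baseline"),
                              names_to = "method", values_to = "mse")
  } else {
    df <- dplyr::mutate(summ[, c("metric", "model")], method = "model",
                        mse = .data$model)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mse,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean squared error", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training loss curve
#' @param object A `train_log` from [train_stage1()] and friends.
#' @param ... Unused.
#' @return A ggplot of per-epoch training loss (log scale).
#' @method autoplot train_log
#' @export
autoplot.train_log <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "training loss (MSE)") +
    ggplot2::theme_minimal()
}

#' Plot observed, imputed, and baseline signal over a genomic window
#'
#' @param tracks Named list of per-bin numeric vectors (e.g.
#'   `list(observed = ..., imputed = ..., average_activity = ...)`).
#' @param grid A [genomic_grid()].
#' @param chrom Chromosome to show (default: first).
#' @param from,to Optional bp range within the chromosome.
#' @return A ggplot with one facet per track.
#' @export
plot_tracks <- function(tracks, grid, chrom = NULL, from = 0, to = NULL) {
  stopifnot(inherits(grid, "genomic_grid"))
  if (is.null(chrom)) chrom <- grid$layout$chrom[1]
  if (is.null(to)) to <- grid$layout$length[match(chrom, grid$layout$chrom)]
  bins <- chromosome_bins(grid, chrom)
  pos <- (bins - min(bins)) * grid$bin_size
  keep <- pos >= from & pos < to
  df <- purrr::imap_dfr(tracks, function(v, nm) {
    tibble::tibble(track = nm, pos = pos[keep], value = v[bins + 1L][keep])
  })
  df$track <- factor(df$track, levels = names(tracks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_area(fill = "#31a354") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$track)) +
    ggplot2::labs(x = sprintf("%s position (bp)", chrom),
                  y = "arcsinh signal") +
    ggplot2::theme_minimal()
}
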