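#' Plot a population response matrix
#'
#' Heatmap of spike counts per cell and presentation, optionally sorted by
#' response similarity first (so the discrete response patterns appear as
#' column blocks).
#'
#' @param object A `v1net_responses` object.
#' @param sort If `TRUE` (default), columns are permuted by
#'   [cluster_and_sort()] leaf order.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot v1net_responses
#' @export
autoplot.v1net_responses <- function(object, sort = TRUE, ...) {
  m <- object$counts
  if (sort && ncol(m) >= 2) m <- cluster_and_sort(m)$counts
  df <- tidyr::expand_grid(cell = seq_len(nrow(m)),
                           presentation = seq_len(ncol(m)))
  df$spikes <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$presentation, .data$cell,
                                   fill = .data$spikes)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = if (sort) "presentation (sorted by similarity)"
                  else "presentation",
                  y = "principal cell", fill = "spikes") +
    ggplot2::theme_minimal()
}

#' Plot a spontaneous-activity spike raster
#'
#' @param object A `v1net_raster` from [record_spontaneous()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot v1net_raster
#' @export
autoplot.v1net_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$neuron,
                                       colour = .data$pop)) +
    ggplot2::geom_point(shape = ".", size = 1) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = "population") +
    ggplot2::theme_minimal()
}

#' Mosaic of reconstructed receptive fields
#'
#' Tiles the signed ON-minus-OFF receptive-field maps of all (or selected)
#' principal cells on a common diverging colour scale.
#'
#' @param network A `v1net` object (or an RF array from [reconstruct_rf()]).
#' @param cells Integer vector of cells to show (default: all).
#' @return A ggplot object.
#' @export
plot_rf_mosaic <- function(network, cells = NULL) {
  rf <- if (is.array(network) && length(dim(network)) == 3) network
        else reconstruct_rf(network)
  n <- dim(rf)[3]
  if (is.null(cells)) cells <- seq_len(n)
  df <- purrr::map_dfr(cells, function(i) {
    tibble::tibble(cell = i,
                   row = rep(seq_len(dim(rf)[1]), times = dim(rf)[2]),
                   col = rep(seq_len(dim(rf)[2]), each = dim(rf)[1]),
                   w = as.vector(rf[, , i]))
  })
  lim <- max(abs(df$w), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~cell) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "navy", high = "firebrick",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "ON - OFF") +
    ggplot2::theme_void()
}

#' Plot mixture-regression coefficient series
#'
#' The two regression coefficients along the stimulus-morphing series; an
#' abrupt crossover indicates competitive, all-or-none population dynamics.
#'
#' @param betas Tibble from [mixture_betas()] (columns `mixture`, `beta1`,
#'   `beta2`), optionally with an extra `condition` column to facet on.
#' @return A ggplot object.
#' @export
plot_mixture_betas <- function(betas) {
  long <- tidyr::pivot_longer(betas, c("beta1", "beta2"),
                              names_to = "coefficient", values_to = "beta")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$mixture, .data$beta,
                                          colour = .data$coefficient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "mixture index (stimulus 2 -> stimulus 1)",
                  y = "regression coefficient") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(betas)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}
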