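#' Tidy a trained network into a long table of lateral weights
#'
#' @param x A `v1net` object.
#' @param ... Unused.
#' @return Tibble with one row per directed lateral E-E connection: `pre`,
#'   `post`, `weight`, `delay_ms`.
#' @method tidy v1net
#' @export
tidy.v1net <- function(x, ...) {
  n <- nrow(x$W_lat)
  idx <- which(row(x$W_lat) != col(x$W_lat), arr.ind = TRUE)
  tibble::tibble(
    post = idx[, 1], pre = idx[, 2],
    weight = x$W_lat[idx],
    delay_ms = x$delays[idx])
}

#' One-row summary of a network's connectivity
#'
#' @param x A `v1net` object.
#' @param ... Unused.
#' @return Tibble with population sizes, training extent, total feedforward
#'   and lateral weight, the transpose-symmetry correlation of the lateral
#'   matrix, and the top-10%/top-5% weight concentration shares.
#' @method glance v1net
#' @export
glance.v1net <- function(x, ...) {
  tibble::tibble(
    n_E = x$config$network$n_E,
    n_I = x$config$network$n_I,
    n_trained = x$n_trained,
    w_ff_sum = sum(x$W_ff),
    w_lat_sum = sum(x$W_lat),
    symmetry = suppressWarnings(weight_symmetry(x$W_lat)),
    top10_share = suppressWarnings(weight_concentration(x$W_lat, 0.10)),
    top5_share = suppressWarnings(weight_concentration(x$W_lat, 0.05)))
}

#' Tidy frozen-network responses into long format
#'
#' @param x A `v1net_responses` object.
#' @param ... Unused.
#' @return Tibble with `cell`, `presentation`, `spikes` and `rate_hz` (over
#'   the stimulus window), plus `potential_mv` when recorded.
#' @method tidy v1net_responses
#' @export
tidy.v1net_responses <- function(x, ...) {
  m <- x$counts
  out <- tibble::tibble(
    cell = rep(seq_len(nrow(m)), times = ncol(m)),
    presentation = rep(seq_len(ncol(m)), each = nrow(m)),
    spikes = as.vector(m),
    rate_hz = as.vector(m) / x$stim_duration * 1000)
  if (!is.null(x$potentials)) out$potential_mv <- as.vector(x$potentials)
  out
}

#' One-row firing-rate summary of a test run
#'
#' @param x A `v1net_responses` object.
#' @param ... Unused.
#' @return The [rate_stats()] tibble plus presentation and cell counts.
#' @method glance v1net_responses
#' @export
glance.v1net_responses <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_cells = nrow(x$counts), n_presentations = ncol(x$counts)),
    rate_stats(x))
}
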