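#' Sample synaptic conduction delays
#'
#' Delays are drawn once, at network construction, from an exponential
#' distribution with median `delay_median` (rate `log(2)/delay_median`),
#' rounded up to whole milliseconds (the integration grid is 1 ms) and floored
#' at `delay_min`. They remain fixed for the whole experiment.
#'
#' @param n Number of delays to draw.
#' @param config A [default_config()] list (network section used).
#' @return Integer vector of delays in ms.
#' @export
sample_delays <- function(n, config = default_config()) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  nc <- config$network
  d <- ceiling(stats::rexp(n, rate = log(2) / nc$delay_median))
  as.integer(pmax(nc$delay_min, d))
}

#' Construct the excitatory/inhibitory network
#'
#' Builds the fully connected network of `n_E` principal and `n_I` inhibitory
#' neurons plus the feedforward ON/OFF input synapses:
#' \itemize{
#'   \item `W_ff` (`n_E` x `2*patch_size^2`): plastic feedforward weights,
#'     initialised uniformly in `(0, w_ff_init_max)`;
#'   \item `W_lat` (`n_E` x `n_E`): plastic lateral E-E weights, initialised
#'     to zero, zero diagonal (no autapses);
#'   \item `W_EI`, `W_IE`, `W_II`: fixed inhibitory-pathway weights drawn
#'     uniformly in `(0, Wmax_*)`, with all weights out of inhibitory cells
#'     switched to negative sign (Dale's law);
#'   \item integer conduction delays for every directed cell pair.
#' }
#' Weight matrices are indexed `[postsynaptic, presynaptic]`.
#'
#' @param config A [default_config()] list.
#' @param seed Optional integer seed (same seed, same network, bit for bit).
#' @return A `v1net` network object.
#' @export
#' @examples
#' net <- build_network(seed = 1)
#' net
build_network <- function(config = default_config(), seed = NULL) {
  config <- validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  nc <- config$network
  n_E <- as.integer(nc$n_E); n_I <- as.integer(nc$n_I)
  n_in <- 2L * config$stimuli$patch_size^2
  n_tot <- n_E + n_I

  W_ff <- matrix(stats::runif(n_E * n_in, 0, nc$w_ff_init_max), n_E, n_in)
  W_lat <- matrix(0, n_E, n_E)
  W_EI <- matrix(stats::runif(n_I * n_E, 0, nc$Wmax_EI), n_I, n_E)
  W_IE <- -matrix(stats::runif(n_E * n_I, 0, nc$Wmax_IE), n_E, n_I)
  W_II <- -matrix(stats::runif(n_I * n_I, 0, nc$Wmax_II), n_I, n_I)
  diag(W_II) <- 0

  delays <- matrix(sample_delays(n_tot * n_tot, config), n_tot, n_tot)
  diag(delays) <- 0L

  structure(list(
    W_ff = W_ff, W_lat = W_lat, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
    delays = delays,
    config = config,
    manipulations = list(silence_inhibition = FALSE,
                         disable_lateral = "none",
                         block_spikes = FALSE),
    n_trained = 0L
  ), class = "v1net")
}

#' Scale a configuration to a larger network
#'
#' Multiplies the excitatory and inhibitory population sizes by `factor` and
#' divides the common lateral multiplier `A_lat` by the same factor, keeping
#' the overall regime of recurrent relative to feedforward input unchanged
#' (e.g. factor 4 gives 400 E / 80 I with `A_lat = 1.25`). All other
#' parameters are untouched.
#'
#' @param config A [default_config()] list.
#' @param factor Integer scaling factor (>= 1).
#' @return Modified configuration.
#' @export
scale_for_size <- function(config, factor) {
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  config$network$n_E <- as.integer(config$network$n_E * factor)
  config$network$n_I <- as.integer(config$network$n_I * factor)
  config$network$A_lat <- config$network$A_lat / factor
  config
}

#' Perturb a configuration for the robustness sweep
#'
#' Multiplies the seven free parameters probed in the robustness analysis
#' (`A_lat`, `Wmax_II`, `Wmax_IE`, `Wmax_EI`, `gamma`, `A_LTP`, `A_LTD`) by a
#' common factor, typically 1.2 or 0.8.
#'
#' @param config A [default_config()] list.
#' @param factor Multiplier applied to all seven parameters.
#' @return Modified configuration.
#' @export
perturb_config <- function(config, factor) {
  for (k in c("A_lat", "Wmax_II", "Wmax_IE", "Wmax_EI")) {
    config$network[[k]] <- config$network[[k]] * factor
  }
  for (k in c("gamma", "A_LTP", "A_LTD")) {
    config$plasticity[[k]] <- config$plasticity[[k]] * factor
  }
  config
}

#' @export
print.v1net <- function(x, ...) {
  nc <- x$config$network
  man <- x$manipulations
  active <- c(
    if (isTRUE(man$silence_inhibition)) "silenced inhibition",
    if (!identical(man$disable_lateral, "none"))
      paste0("lateral disabled (", man$disable_lateral, ")"),
    if (isTRUE(man$block_spikes)) "spike blocking"
  )
  cat("<v1net> ", nc$n_E, " E + ", nc$n_I, " I neurons, ",
      ncol(x$W_ff), " feedforward inputs\n", sep = "")
  cat("  trained presentations: ", x$n_trained, "\n", sep = "")
  cat("  lateral E-E weight sum: ", format(sum(x$W_lat), digits = 4), "\n", sep = "")
  if (length(active)) cat("  manipulations: ", paste(active, collapse = ", "),
                          "\n", sep = "")
  invisible(x)
}

#' Write a network to a directory of plain-text files
#'
#' Serialises each weight matrix and the delay matrix as CSV and the full
#' configuration as YAML, for inspection or later reloading with
#' [read_network()].
#'
#' @param network A `v1net` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("W_ff", "W_lat", "W_EI", "W_IE", "W_II", "delays")) {
    utils::write.table(network[[nm]], file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  save_config(network$config, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(manipulations = network$manipulations,
                        n_trained = network$n_trained),
                   file.path(dir, "state.yaml"))
  invisible(dir)
}

#' @rdname write_network
#' @param dir Directory written by [write_network()].
#' @export
read_network <- function(dir) {
  net <- list()
  for (nm in c("W_ff", "W_lat", "W_EI", "W_IE", "W_II", "delays")) {
    net[[nm]] <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                             sep = ","))
    dimnames(net[[nm]]) <- NULL
  }
  net$delays <- matrix(as.integer(net$delays), nrow(net$delays))
  net$config <- load_config(file.path(dir, "config.yaml"))
  st <- yaml::read_yaml(file.path(dir, "state.yaml"))
  net$manipulations <- st$manipulations
  net$n_trained <- st$n_trained
  structure(net, class = "v1net")
}
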