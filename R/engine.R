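run_engine <- function(network, rates, plastic,
                       stim_duration = NULL, blank_duration = NULL,
                       record_spikes = FALSE, record_potentials = FALSE,
                       checkpoint_at = integer(0), seed = NULL,
                       verbose_every = 0L) {
  cfg <- network$config
  if (is.null(stim_duration)) stim_duration <- cfg$protocol$stim_duration
  if (is.null(blank_duration)) blank_duration <- cfg$protocol$blank_duration
  if (!is.null(seed)) set.seed(seed)
  man <- network$manipulations
  dl <- switch(man$disable_lateral, none = 0L, ee = 1L, all = 2L,
               stop("unknown disable_lateral mode", call. = FALSE))
  plast <- cfg$plasticity
  plast$theta_minus <- plast$theta_minus %||% cfg$neuron$E_l
  cpp_run_network(
    network$W_ff, network$W_lat, network$W_EI, network$W_IE, network$W_II,
    network$delays, rates,
    as.integer(stim_duration), as.integer(blank_duration),
    plastic,
    cfg$neuron, plast, cfg$network,
    isTRUE(man$silence_inhibition), dl, isTRUE(man$block_spikes),
    record_spikes, record_potentials,
    as.integer(checkpoint_at), as.integer(verbose_every))
}

#' Train the network on a stimulus stream
#'
#' Presents each stimulus for `stim_duration` ms of Poisson input followed by
#' `blank_duration` ms of null input, with the plasticity rule active at both
#' feedforward and lateral E-E synapses throughout. Optionally snapshots the
#' weight matrices at chosen presentations for stabilization statistics.
#'
#' @param network A `v1net` object from [build_network()].
#' @param stimuli A `v1net_stimuli` object; its columns are presented in order.
#' @param n_presentations Number of presentations; if larger than the number
#'   of patches the stream cycles. Defaults to all patches once.
#' @param checkpoint_at Integer vector of presentation indices after which the
#'   flattened `W_lat`/`W_ff` are snapshotted.
#' @param seed Optional seed for the simulation (noise and input spike draws).
#' @param verbose_every If > 0, log mean rate and weight sums every that many
#'   presentations.
#' @return The trained network, with element `history` carrying checkpoints
#'   and per-presentation spike counts.
#' @export
train_network <- function(network, stimuli, n_presentations = NULL,
                          checkpoint_at = integer(0), seed = NULL,
                          verbose_every = 0L) {
  rates <- stimuli$on_off * stimuli$rate_scale
  n_avail <- ncol(rates)
  if (!is.null(n_presentations) && n_presentations != n_avail) {
    idx <- rep_len(seq_len(n_avail), n_presentations)
    rates <- rates[, idx, drop = FALSE]
  }
  res <- run_engine(network, rates, plastic = TRUE,
                    checkpoint_at = checkpoint_at, seed = seed,
                    verbose_every = verbose_every)
  network$W_ff <- res$W_ff
  network$W_lat <- res$W_lat
  network$n_trained <- network$n_trained + ncol(rates)
  network$history <- list(
    checkpoint_at = res$checkpoint_at,
    checkpoints_lat = res$checkpoints_lat,
    checkpoints_ff = res$checkpoints_ff,
    counts_stim = res$counts_stim,
    total_spikes_E = res$total_spikes_E,
    total_spikes_I = res$total_spikes_I)
  network
}

#' Record frozen-network responses to a stimulus set
#'
#' Presents each stimulus with all plasticity disabled (weights frozen) and
#' records the total spike count of every principal cell per presentation,
#' optionally together with each cell's mean subthreshold potential over the
#' stimulus window (spike-crest samples excluded).
#'
#' @inheritParams train_network
#' @param record_potentials Record mean subthreshold potentials as well.
#' @param record_spikes Keep the full spike raster (time-resolved).
#' @return A `v1net_responses` object: `counts` (`n_E` x presentations, spikes
#'   in the stimulus window), `counts_blank`, optional `potentials`, the
#'   protocol durations, and the stimulus metadata.
#' @export
test_responses <- function(network, stimuli, record_potentials = FALSE,
                           record_spikes = FALSE, seed = NULL) {
  rates <- stimuli$on_off * stimuli$rate_scale
  res <- run_engine(network, rates, plastic = FALSE,
                    record_spikes = record_spikes,
                    record_potentials = record_potentials, seed = seed)
  structure(list(
    counts = res$counts_stim,
    counts_blank = res$counts_blank,
    potentials = if (record_potentials) res$potentials,
    raster = if (record_spikes)
      tibble::tibble(time_ms = res$spike_time, neuron = res$spike_id),
    stim_duration = network$config$protocol$stim_duration,
    blank_duration = network$config$protocol$blank_duration,
    meta = stimuli$meta,
    order = seq_len(ncol(res$counts_stim))
  ), class = "v1net_responses")
}

#' Record spontaneous activity
#'
#' Runs the frozen network with feedforward rates identically zero, so all
#' activity is driven by the constant barrage of background noise spikes, and
#' returns the spike raster.
#'
#' @param network A `v1net` object (weights are frozen during recording).
#' @param duration Recording duration in ms (default 100 s, enough to
#'   populate 50-ms-bin statistics).
#' @param seed Optional seed.
#' @return A `v1net_raster` tibble with columns `time_ms`, `neuron`, `pop`
#'   (`"E"`/`"I"`) and attributes `duration`, `n_E`, `n_I`.
#' @export
record_spontaneous <- function(network, duration = 100000, seed = NULL) {
  n_in <- ncol(network$W_ff)
  rates <- matrix(0, n_in, 1)
  res <- run_engine(network, rates, plastic = FALSE,
                    stim_duration = duration, blank_duration = 0,
                    record_spikes = TRUE, seed = seed)
  n_E <- network$config$network$n_E
  out <- tibble::tibble(
    time_ms = res$spike_time,
    neuron = res$spike_id,
    pop = ifelse(res$spike_id <= n_E, "E", "I"))
  structure(out, duration = duration, n_E = n_E,
            n_I = network$config$network$n_I,
            class = c("v1net_raster", class(out)))
}

#' Apply a network manipulation
#'
#' The three manipulations probed on the trained network:
#' \describe{
#'   \item{`silence_inhibition`}{inhibitory neurons are silenced (cannot
#'     spike); the excitatory network is untouched.}
#'   \item{`disable_lateral`}{lateral inputs are removed; `scope = "all"`
#'     removes every connection between cells (excitatory and inhibitory),
#'     `scope = "ee"` removes only the lateral E-E connections.}
#'   \item{`block_spikes`}{the exponential spike-initiation term is removed
#'     from every cell, blocking spiking while leaving subthreshold dynamics
#'     intact.}
#'   \item{`none`}{clears all manipulations.}
#' }
#'
#' @param network A `v1net` object.
#' @param kind One of `"silence_inhibition"`, `"disable_lateral"`,
#'   `"block_spikes"`, `"none"`.
#' @param scope For `disable_lateral`: `"all"` (default) or `"ee"`.
#' @return The network with the manipulation flag set.
#' @export
apply_manipulation <- function(network,
                               kind = c("silence_inhibition", "disable_lateral",
                                        "block_spikes", "none"),
                               scope = c("all", "ee")) {
  kind <- match.arg(kind)
  scope <- match.arg(scope)
  if (kind == "none") {
    network$manipulations <- list(silence_inhibition = FALSE,
                                  disable_lateral = "none",
                                  block_spikes = FALSE)
  } else if (kind == "silence_inhibition") {
    network$manipulations$silence_inhibition <- TRUE
  } else if (kind == "disable_lateral") {
    network$manipulations$disable_lateral <- scope
  } else {
    network$manipulations$block_spikes <- TRUE
  }
  network
}

#' @export
print.v1net_responses <- function(x, ...) {
  cat("<v1net_responses> ", nrow(x$counts), " cells x ", ncol(x$counts),
      " presentations (", x$stim_duration, "+", x$blank_duration, " ms)\n",
      sep = "")
  if (!is.null(x$potentials)) cat("  with mean subthreshold potentials\n")
  invisible(x)
}
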