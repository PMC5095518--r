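#' Initial plasticity traces
#'
#' Per-neuron voltage traces and per-synapse presynaptic spike traces used by
#' the voltage-dependent STDP rule: `u_plus` (short time constant, gates LTP's
#' "recently depolarized" term), `u_minus` (slightly longer, drives LTD),
#' `u_long` (slow ~20 s homeostatic trace of how far the voltage lies above
#' the LTP threshold `theta_plus`), and `x_bar` (exponential trace of
#' presynaptic spike arrivals, one per synapse).
#'
#' @param u0 Initial membrane potential (mV); voltage traces start there.
#' @param n_syn Number of presynaptic sources for `x_bar`.
#' @return Named list of traces.
#' @export
plasticity_traces <- function(u0 = -70.6, n_syn = 1L) {
  list(u_plus = u0, u_minus = u0, u_long = 0, x_bar = numeric(n_syn))
}

#' Advance the plasticity traces by one Euler step
#'
#' Each voltage trace relaxes toward its drive with its own time constant:
#' `u_plus` and `u_minus` toward the current (post-clipping) membrane voltage,
#' `u_long` toward the half-rectified excess of the voltage above
#' `theta_plus` (so only the stereotyped spike crest feeds the homeostatic
#' trace). The presynaptic trace `x_bar` decays with `tau_x` and increments by
#' 1 for every synapse at which a presynaptic spike arrived this step.
#'
#' @param traces List from [plasticity_traces()].
#' @param u Post-clipping membrane voltage this step (mV).
#' @param presyn_arrivals Binary (0/1) vector, one entry per synapse.
#' @param params Plasticity parameter list (`plasticity` section of
#'   [default_config()]).
#' @param dt Timestep (ms).
#' @return Updated traces.
#' @export
update_traces <- function(traces, u, presyn_arrivals = 0,
                          params = default_config()$plasticity, dt = 1) {
  traces$u_plus  <- traces$u_plus  + dt / params$tau_uplus  * (u - traces$u_plus)
  traces$u_minus <- traces$u_minus + dt / params$tau_uminus * (u - traces$u_minus)
  drive <- max(u - theta_plus(params), 0)
  traces$u_long <- traces$u_long + dt / params$tau_long * (drive - traces$u_long)
  traces$x_bar <- traces$x_bar * (1 - dt / params$tau_x) + presyn_arrivals
  traces
}

#' LTP voltage threshold
#'
#' The plasticity threshold `theta_plus` is tied to the firing threshold as
#' `(V_TMAX + V_Trest) / 2`; it is derived from the neuron section rather than
#' stored, so the invariant holds by construction.
#'
#' @param plast_params Plasticity parameter list (may carry `theta_plus`
#'   pre-computed by the engine).
#' @param neuron_params Neuron parameter list used for the derivation.
#' @return `theta_plus` in mV.
#' @export
theta_plus <- function(plast_params = NULL,
                       neuron_params = default_config()$neuron) {
  if (!is.null(plast_params$theta_plus)) return(plast_params$theta_plus)
  (neuron_params$V_TMAX + neuron_params$V_Trest) / 2
}

#' Depression update for one synapse
#'
#' LTD fires on presynaptic spike arrival (`X = 1`), proportionally to the
#' recent depolarization (half-rectified excess of the `u_minus` trace above
#' `theta_minus`, the resting potential) and to the square of the long-term
#' above-threshold trace relative to its reference: the homeostatic factor
#' `(u_long / u_ref)^2` makes depression a superlinear function of sustained
#' firing.
#'
#' @param w Current weight (unused by LTD; kept for a uniform signature).
#' @param traces Current traces.
#' @param X Binary presynaptic arrival indicator.
#' @param params Plasticity parameter list.
#' @return Non-positive weight change.
#' @export
ltd_delta <- function(w, traces, X, params = default_config()$plasticity) {
  if (X <= 0) return(0)
  -params$A_LTD * max(traces$u_minus - params$theta_minus, 0) *
    (traces$u_long / params$u_ref)^2
}

#' Potentiation update for one synapse
#'
#' LTP requires the membrane voltage to exceed the high threshold
#' `theta_plus` (which, given the stereotyped spike crest, happens during
#' spikes), the cell to have been recently depolarized (`u_plus` above
#' `theta_minus`), and a presynaptic spike in the recent past (`x_bar > 0`).
#' Potentiation is attenuated by the current weight through the factor
#' `1 / (gamma * (w + w_eps))`: larger weights are harder to increase, which
#' replaces a hard weight ceiling and yields graded weight distributions. The
#' small `w_eps` keeps the factor finite at `w = 0`, so the zero-initialised
#' lateral weights can begin to grow.
#'
#' @param w Current weight (>= 0).
#' @param traces Current traces (with `x_bar` for this synapse).
#' @param u Post-clipping membrane voltage this step (mV).
#' @param params Plasticity parameter list.
#' @param x_bar Presynaptic trace value for this synapse (defaults to
#'   `traces$x_bar[1]`).
#' @return Non-negative weight change.
#' @export
ltp_delta <- function(w, traces, u, params = default_config()$plasticity,
                      x_bar = traces$x_bar[1]) {
  gate <- max(u - theta_plus(params), 0) * max(traces$u_plus - params$theta_minus, 0)
  if (gate <= 0 || x_bar <= 0) return(0)
  params$A_LTP * x_bar * gate / (params$gamma * (w + params$w_eps))
}

#' Apply a weight change with the hard floor at zero
#'
#' Weights from excitatory neurons are clipped from below at zero (Dale's
#' law); there is no upper clip (the weight-dependent LTP factor bounds growth
#' instead).
#'
#' @param w Current weight (>= 0).
#' @param delta Proposed change.
#' @return `max(w + delta, 0)`.
#' @export
apply_update <- function(w, delta) {
  pmax(w + delta, 0)
}
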