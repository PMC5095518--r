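#' Initial state of an AdEx neuron
#'
#' @param params Neuron parameter list (the `neuron` section of
#'   [default_config()]).
#' @return Named list: membrane potential `u` (mV, at rest), adaptive threshold
#'   `V_T`, adaptation current `w_ad` (pA), spike afterpotential `z` (pA), and
#'   `clip_countdown` (1 while the voltage is held at the spike crest).
#' @export
neuron_state <- function(params) {
  list(u = params$E_l, V_T = params$V_Trest, w_ad = 0, z = 0,
       clip_countdown = 0L)
}

#' One 1-ms Euler step of the adaptive exponential neuron
#'
#' Advances the membrane potential by forward Euler with the fixed 1-ms grid
#' the whole simulation uses: leak, exponential spike-initiation term (if
#' enabled), hyperpolarizing adaptation `w_ad`, depolarizing afterpotential
#' `z`, plus the summed synaptic and noise currents. The adaptive threshold
#' decays toward `V_Trest`, `w_ad` and `z` decay toward zero. A spike is
#' registered when `u` reaches `V_PEAK`; the voltage is then clipped to
#' `V_PEAK` (see [apply_spike()]). While the neuron is in the 1-ms clipped
#' crest the membrane is not integrated: the crest step reports `u = V_PEAK`
#' and the state then resets to `E_l`.
#'
#' The exponential argument `(u - V_T)/Delta_T` is capped at
#' `params$exp_cap` so the Euler overshoot saturates instead of overflowing;
#' the clip-to-`V_PEAK` convention makes the exact overshoot value irrelevant.
#'
#' @param state Neuron state from [neuron_state()].
#' @param I_FF,I_Lat,I_inh,I_noise Input currents in pA (I_inh is negative).
#' @param params Neuron parameter list.
#' @param dt Timestep (ms); the integration contract is `dt = 1`.
#' @param exponential_enabled If `FALSE`, the spike-initiation term is removed
#'   (the spike-blocking manipulation).
#' @return List `(state, spiked)`. `spiked` is `TRUE` exactly once per
#'   threshold crossing; call [apply_spike()] when it is.
#' @export
adex_step <- function(state, I_FF = 0, I_Lat = 0, I_inh = 0, I_noise = 0,
                      params = default_config()$neuron, dt = 1,
                      exponential_enabled = TRUE) {
  inputs <- c(I_FF, I_Lat, I_inh, I_noise)
  if (!all(is.finite(c(state$u, state$V_T, state$w_ad, state$z, inputs)))) {
    stop("non-finite neuron state or input current", call. = FALSE)
  }
  if (state$clip_countdown > 0L) {
    # crest step: voltage held at V_PEAK; no integration, no new spike
    state$u <- params$V_PEAK
    state$clip_countdown <- 0L
    state$V_T <- state$V_T + dt / params$tau_VT * (params$V_Trest - state$V_T)
    state$w_ad <- state$w_ad * (1 - dt / params$tau_wad)
    state$z <- state$z * (1 - dt / params$tau_z)
    return(list(state = state, spiked = FALSE))
  }
  # u == V_PEAK with countdown 0 can only follow a crest step (a natural
  # crossing always goes through apply_spike): reset to rest before integrating
  u <- if (state$u >= params$V_PEAK) params$E_l else state$u
  expo <- 0
  if (exponential_enabled) {
    arg <- min((u - state$V_T) / params$Delta_T, params$exp_cap)
    expo <- params$g_l * params$Delta_T * exp(arg)
  }
  du <- dt / params$C *
    (-params$g_l * (u - params$E_l) + expo - state$w_ad + state$z + sum(inputs))
  u_new <- u + du
  state$V_T <- state$V_T + dt / params$tau_VT * (params$V_Trest - state$V_T)
  state$w_ad <- state$w_ad * (1 - dt / params$tau_wad)
  state$z <- state$z * (1 - dt / params$tau_z)
  spiked <- u_new >= params$V_PEAK
  state$u <- if (spiked) params$V_PEAK else u_new
  list(state = state, spiked = spiked)
}

#' Post-spike adjustments
#'
#' Applies the stereotyped spike: the voltage is clipped to `V_PEAK` for one
#' further 1-ms step (then reset to `E_l` by [adex_step()]), the adaptive
#' threshold jumps to `V_TMAX`, the adaptation current increments by `b_wad`,
#' and the afterpotential is set to `I_sp`.
#'
#' @param state Neuron state for which a spike was detected this step.
#' @param params Neuron parameter list.
#' @return Updated state with `clip_countdown = 1`.
#' @export
apply_spike <- function(state, params = default_config()$neuron) {
  state$u <- params$V_PEAK
  state$V_T <- params$V_TMAX
  state$w_ad <- state$w_ad + params$b_wad
  state$z <- params$I_sp
  state$clip_countdown <- 1L
  state
}

#' Disable the spike-initiation term (spike blocking)
#'
#' Returns a parameter list with the exponential component of the AdEx
#' equation removed, so runaway depolarization (and hence spiking under any
#' realistic bounded input) cannot occur while subthreshold dynamics are
#' otherwise identical. [unblock_spiking()] restores the original parameters
#' exactly.
#'
#' @param params Neuron parameter list.
#' @return Parameter list with `exponential_enabled = FALSE` recorded.
#' @export
block_spiking <- function(params) {
  params$exponential_enabled <- FALSE
  params
}

#' @rdname block_spiking
#' @export
unblock_spiking <- function(params) {
  params$exponential_enabled <- NULL
  params
}

#' Simulate a single AdEx neuron under constant input
#'
#' Convenience wrapper used for unit tests and illustrations: iterates
#' [adex_step()]/[apply_spike()] for `n_steps` 1-ms steps under a constant
#' injected current.
#'
#' @param I Constant input current (pA).
#' @param n_steps Number of 1-ms steps.
#' @param params Neuron parameter list (possibly from [block_spiking()]).
#' @param u0 Initial membrane potential (default rest).
#' @return Tibble with columns `t` (ms), `u` (mV), `spiked`.
#' @export
simulate_adex <- function(I, n_steps, params = default_config()$neuron,
                          u0 = NULL) {
  exp_on <- !isFALSE(params$exponential_enabled)
  st <- neuron_state(params)
  if (!is.null(u0)) st$u <- u0
  u <- numeric(n_steps); sp <- logical(n_steps)
  for (t in seq_len(n_steps)) {
    res <- adex_step(st, I_FF = I, params = params, exponential_enabled = exp_on)
    st <- res$state
    u[t] <- st$u
    sp[t] <- res$spiked
    if (res$spiked) st <- apply_spike(st, params)
  }
  tibble::tibble(t = seq_len(n_steps), u = u, spiked = sp)
}
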