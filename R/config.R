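#' Default model configuration
#'
#' Returns the full nested configuration of the model: stimulus pre-processing,
#' neuron dynamics, plasticity rule, network architecture and presentation
#' protocol. Every numeric parameter of the model lives here; all constructors
#' and simulation entry points accept a config produced by this function (or by
#' [load_config()]) so experiments are fully specified by one object plus a seed.
#'
#' Membrane parameters follow the standard adaptive exponential
#' integrate-and-fire parameterisation (capacitance in pF, conductance in nS,
#' voltages in mV, currents in pA, time in ms); the plasticity section follows
#' the voltage-dependent STDP rule with weight-dependent potentiation (see the
#' package vignette for the equations and for how the free scale factors were
#' calibrated).
#'
#' @return A nested named list of class `v1net_config` with sections
#'   `stimuli`, `neuron`, `plasticity`, `network` and `protocol`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$network$A_lat
default_config <- function() {
  cfg <- list(
    stimuli = list(
      patch_size     = 17L,    # pixels per side
      sigma_center   = 1,      # DoG centre s.d. (px)
      sigma_surround = 2,      # DoG surround s.d. (px)
      rate_scale     = 800,    # Hz of input firing per unit |intensity| (calibrated)
      image_size     = 128L,   # synthetic image side (px)
      spectral_exponent = 1    # amplitude ~ 1/f^exponent
    ),
    neuron = list(
      C        = 281,     # membrane capacitance (pF)
      g_l      = 30,      # leak conductance (nS)
      E_l      = -70.6,   # resting potential (mV)
      Delta_T  = 2,       # spike slope factor (mV)
      V_Trest  = -50.4,   # resting threshold (mV)
      V_TMAX   = -30.4,   # post-spike threshold (mV)
      tau_VT   = 50,      # threshold decay (ms)
      b_wad    = 80.5,    # adaptation increment per spike (pA)
      tau_wad  = 144,     # adaptation decay (ms)
      I_sp     = 400,     # spike afterpotential amplitude (pA)
      tau_z    = 40,      # afterpotential decay (ms)
      V_PEAK   = 20,      # spike detection / clipping voltage (mV)
      exp_cap  = 20       # cap on (u - V_T)/Delta_T inside exp() (overflow guard)
    ),
    plasticity = list(
      A_LTD      = 8e-3,   # LTD rate (weight units per mV of u_minus excess)
      A_LTP      = 1e-2,   # LTP rate (weight units per mV^2, before 1/(gamma w))
      tau_uplus  = 7,      # short voltage trace, gates LTP (ms)
      tau_uminus = 10,     # slightly longer voltage trace, drives LTD (ms)
      tau_long   = 20000,  # long homeostatic trace (ms)
      tau_x      = 15,     # presynaptic spike trace (ms)
      theta_minus = -70.6, # rectification floor for u_minus / u_plus (mV, = E_l)
      u_ref      = 1.3,    # homeostatic reference for the long trace (mV)
      gamma      = 15,     # weight-dependence scale of LTP
      w_eps      = 5       # regulariser so zero-initialised weights can potentiate
    ),
    network = list(
      n_E          = 100L,
      n_I          = 20L,
      A_lat        = 5.0,   # common multiplier of all lateral inputs
      Wmax_EI      = 100,   # E -> I fixed weights ~ U(0, Wmax_EI), pA per spike
      Wmax_IE      = 100,   # I -> E, drawn positive then negated
      Wmax_II      = 100,   # I -> I, drawn positive then negated
      w_ff_init_max = 30,   # feedforward init ~ U(0, w_ff_init_max)
      delay_median = 4,     # ms
      delay_min    = 1,     # ms
      noise_rate   = 1800,  # Hz of excitatory noise spikes per cell
      w_noise      = 260    # pA per noise spike
    ),
    protocol = list(
      stim_duration  = 300L,  # ms of stimulus per presentation
      blank_duration = 50L,   # ms of null input between presentations
      n_train        = 50000L, # scaled-down training horizon (presentations)
      n_test         = 1000L
    )
  )
  structure(cfg, class = "v1net_config")
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file and merges it
#' over [default_config()]. Only keys present in the defaults are allowed;
#' unknown keys raise an error naming the offending key, so typos cannot
#' silently fall back to defaults. An empty file yields the pure defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated `v1net_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      stop("unknown config section: '", section, "'", call. = FALSE)
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop("unknown config key: '", section, "$", key, "'", call. = FALSE)
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  validate_config(cfg)
}

#' Save a configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, f))` returns `cfg`.
#'
#' @param config A `v1net_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  num_pos <- function(section, keys) {
    for (k in keys) {
      v <- cfg[[section]][[k]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
        stop("config parameter ", section, "$", k,
             " must be a single positive finite number", call. = FALSE)
      }
    }
  }
  num_pos("neuron", c("C", "g_l", "Delta_T", "tau_VT", "tau_wad", "tau_z"))
  num_pos("plasticity", c("tau_uplus", "tau_uminus", "tau_long", "tau_x",
                          "u_ref", "gamma"))
  num_pos("network", c("n_E", "n_I", "A_lat", "Wmax_EI", "Wmax_IE", "Wmax_II"))
  num_pos("stimuli", c("sigma_center", "sigma_surround"))
  n <- cfg$neuron
  if (!(n$V_Trest < n$V_TMAX && n$V_TMAX < n$V_PEAK)) {
    stop("config requires V_Trest < V_TMAX < V_PEAK", call. = FALSE)
  }
  if (cfg$stimuli$sigma_center >= cfg$stimuli$sigma_surround) {
    stop("config requires sigma_center < sigma_surround", call. = FALSE)
  }
  if (cfg$stimuli$rate_scale < 0) {
    stop("config parameter stimuli$rate_scale must be non-negative", call. = FALSE)
  }
  if (cfg$network$delay_min < 1) {
    stop("config parameter network$delay_min must be >= 1 ms", call. = FALSE)
  }
  if (cfg$network$noise_rate < 0 || cfg$network$w_noise < 0) {
    stop("noise_rate and w_noise must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "v1net_config")
}

#' Derive named per-component seeds from a single global seed
#'
#' One global seed fans out to fixed-offset seeds for the independent random
#' components (stimulus generation, network construction, simulation noise) so
#' that, e.g., changing the stimulus stream does not perturb network
#' construction. Offsets keep all seeds below 2^31.
#'
#' @param seed A single integer.
#' @return Named integer vector with elements `stimuli`, `network`, `sim`,
#'   `test`.
#' @export
seed_streams <- function(seed) {
  seed <- as.integer(seed)
  base <- (abs(seed) %% 1000000000L)
  c(stimuli = base + 101L, network = base + 202L,
    sim = base + 303L, test = base + 404L)
}

#' @export
print.v1net_config <- function(x, ...) {
  cat("<v1net_config>\n")
  for (s in names(x)) {
    vals <- vapply(x[[s]], function(v) format(v), character(1))
    cat("  ", s, ": ", paste0(names(vals), "=", vals, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
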