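test_that("a silent network stays silent and at rest", {
  cfg <- tiny_config(n_E = 3, n_I = 1)
  net <- build_network(cfg, seed = 1)
  stim <- raw_stimuli(matrix(0, 578, 2), rate_scale = 0)
  resp <- test_responses(net, stim, seed = 2)
  expect_equal(sum(resp$counts), 0)
  expect_equal(sum(resp$counts_blank), 0)
})

test_that("simulation runs are bit-identical for identical seed and config", {
  cfg <- tiny_config(n_E = 5, n_I = 2, noise_rate = 1800, w_noise = 230)
  net <- build_network(cfg, seed = 3)
  on_off <- matrix(runif(578 * 4), 578, 4)
  stim <- raw_stimuli(on_off, rate_scale = 150)
  r1 <- test_responses(net, stim, record_spikes = TRUE, seed = 7)
  r2 <- test_responses(net, stim, record_spikes = TRUE, seed = 7)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$raster, r2$raster)
  r3 <- test_responses(net, stim, record_spikes = TRUE, seed = 8)
  expect_false(identical(r1$raster, r3$raster))

  # training is equally deterministic
  t1 <- train_network(net, stim, seed = 9)
  t2 <- train_network(net, stim, seed = 9)
  expect_identical(t1$W_ff, t2$W_ff)
  expect_identical(t1$W_lat, t2$W_lat)
})

test_that("a presynaptic spike reaches its target exactly after the conduction delay", {
  cfg <- tiny_config(n_E = 2, n_I = 1, stim = 120, blank = 0)
  for (d in c(2L, 7L)) {
    net <- build_network(cfg, seed = 4)
    # isolate the E1 -> E2 synapse: no inhibition, no E2 feedforward drive
    net$W_IE[] <- 0; net$W_II[] <- 0; net$W_EI[] <- 0
    net$W_ff[2, ] <- 0
    net$W_ff[1, ] <- 40                     # strong drive to cell 1 only
    net$W_lat[2, 1] <- 6000                 # suprathreshold single-arrival kick
    net$delays[2, 1] <- d
    on_off <- matrix(0, 578, 1); on_off[1:50, 1] <- 1
    stim <- raw_stimuli(on_off, rate_scale = 1000)
    r <- test_responses(net, stim, record_spikes = TRUE, seed = 5)
    t1 <- min(r$raster$time_ms[r$raster$neuron == 1])
    t2 <- min(r$raster$time_ms[r$raster$neuron == 2])
    # arrival at t1 + d drives the crossing in that same step
    expect_equal(t2 - t1, d)

    # with lateral E-E connections disabled the follower never fires
    ra <- test_responses(apply_manipulation(net, "disable_lateral", "ee"),
                         stim, record_spikes = TRUE, seed = 5)
    expect_gt(sum(ra$raster$neuron == 1), 0)
    expect_equal(sum(ra$raster$neuron == 2), 0)
  }
})

test_that("doubling the noise rate increases spontaneous activity", {
  cfg <- tiny_config(n_E = 10, n_I = 2, noise_rate = 1800, w_noise = 230)
  net <- build_network(cfg, seed = 6)
  ras1 <- record_spontaneous(net, duration = 5000, seed = 11)
  cfg2 <- cfg; cfg2$network$noise_rate <- 3600
  net2 <- net; net2$config <- validate_config(cfg2)
  ras2 <- record_spontaneous(net2, duration = 5000, seed = 11)
  expect_gt(nrow(ras2), nrow(ras1))

  cfg0 <- cfg; cfg0$network$noise_rate <- 0
  net0 <- net; net0$config <- validate_config(cfg0)
  ras0 <- record_spontaneous(net0, duration = 2000, seed = 11)
  expect_equal(nrow(ras0), 0)
})

test_that("manipulations follow their contracts on a toy network", {
  cfg <- tiny_config(n_E = 8, n_I = 3, noise_rate = 1800, w_noise = 260,
                     stim = 200, blank = 0)
  cfg$network$Wmax_EI <- 300; cfg$network$Wmax_IE <- 600
  net <- build_network(cfg, seed = 12)
  net$W_lat[] <- 700; diag(net$W_lat) <- 0    # strong recurrent excitation

  spont <- function(n) record_spontaneous(n, duration = 4000, seed = 13)
  full <- spont(net)
  silenced <- spont(apply_manipulation(net, "silence_inhibition"))
  ablated <- spont(apply_manipulation(
    apply_manipulation(net, "silence_inhibition"), "disable_lateral"))

  # silencing removes every inhibitory spike but leaves E cells active
  expect_gt(sum(full$pop == "I"), 0)
  expect_equal(sum(silenced$pop == "I"), 0)
  # without inhibition the recurrent excitation raises E firing; ablating the
  # lateral connections as well collapses it back to the noise-driven floor
  expect_gt(sum(silenced$pop == "E"), sum(full$pop == "E"))
  expect_lt(sum(ablated$pop == "E"), sum(silenced$pop == "E") / 5)

  # spike blocking: depolarization without a single spike
  blocked <- apply_manipulation(net, "block_spikes")
  on_off <- matrix(1, 578, 2)
  stim <- raw_stimuli(on_off, rate_scale = 100)
  rb <- test_responses(blocked, stim, record_potentials = TRUE, seed = 14)
  expect_equal(sum(rb$counts), 0)
  expect_true(all(rb$potentials > -80) && all(rb$potentials < 20))
  expect_gt(mean(rb$potentials), -70.6)   # depolarized above rest

  expect_error(apply_manipulation(net, "melt"), "arg")
})

test_that("frozen-network potential recording excludes spike crests", {
  cfg <- tiny_config(n_E = 2, n_I = 1, stim = 150, blank = 0)
  net <- build_network(cfg, seed = 15)
  net$W_ff[1, ] <- 60; net$W_ff[2, ] <- 0
  net$W_IE[] <- 0; net$W_EI[] <- 0
  on_off <- matrix(0, 578, 1); on_off[1:60, 1] <- 1
  stim <- raw_stimuli(on_off, rate_scale = 800)
  r <- test_responses(net, stim, record_potentials = TRUE, seed = 16)
  expect_gt(r$counts[1, 1], 0)
  # mean subthreshold potential stays below the spike crest value
  expect_lt(r$potentials[1, 1], 0)
  expect_gt(r$potentials[1, 1], -70.6)
})

test_that("engine and R reference neuron implementation agree on a noiseless trajectory", {
  # one neuron, constant feedforward drive, no noise/inhibition/laterals:
  # the engine's spike times must match the R-level adex_step loop exactly
  cfg <- tiny_config(n_E = 1, n_I = 1, stim = 400, blank = 0)
  net <- build_network(cfg, seed = 17)
  net$W_IE[] <- 0; net$W_EI[] <- 0
  net$W_ff[1, ] <- 0; net$W_ff[1, 1] <- 750
  on_off <- matrix(0, 578, 1); on_off[1, 1] <- 1
  stim <- raw_stimuli(on_off, rate_scale = 1000)  # p = 1: a spike every ms
  r <- test_responses(net, stim, record_spikes = TRUE, seed = 18)
  engine_times <- sort(r$raster$time_ms[r$raster$neuron == 1])

  traj <- simulate_adex(750, 400, default_config()$neuron)
  ref_times <- traj$t[traj$spiked] - 1L   # engine time is 0-based
  expect_equal(engine_times, ref_times)
})

test_that("training records checkpoints at the requested presentations", {
  cfg <- tiny_config(n_E = 4, n_I = 2, noise_rate = 900, w_noise = 260,
                     stim = 60, blank = 20)
  net <- build_network(cfg, seed = 19)
  stim <- raw_stimuli(matrix(runif(578 * 10), 578, 10), rate_scale = 120)
  tr <- train_network(net, stim, n_presentations = 10, checkpoint_at = c(5, 10),
                      seed = 20)
  expect_equal(tr$history$checkpoint_at, c(5, 10))
  expect_length(tr$history$checkpoints_lat, 2)
  expect_length(tr$history$checkpoints_lat[[1]], 16)
  # final checkpoint equals the returned weights
  expect_equal(as.vector(tr$W_lat), as.vector(tr$history$checkpoints_lat[[2]]))
  expect_equal(tr$n_trained, 10L)
})

test_that("structural invariants hold after training", {
  cfg <- tiny_config(n_E = 6, n_I = 2, noise_rate = 1800, w_noise = 230,
                     stim = 80, blank = 20)
  net <- build_network(cfg, seed = 21)
  stim <- raw_stimuli(matrix(runif(578 * 20), 578, 20), rate_scale = 200)
  tr <- train_network(net, stim, n_presentations = 20, seed = 22)
  expect_true(all(tr$W_ff >= 0))
  expect_true(all(tr$W_lat >= 0))
  expect_equal(diag(tr$W_lat), numeric(6))   # no autapses ever
  expect_identical(tr$W_IE, net$W_IE)        # inhibitory weights fixed
  expect_identical(tr$W_EI, net$W_EI)
  expect_identical(tr$W_II, net$W_II)
  expect_identical(tr$delays, net$delays)
})
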