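# Fixed-step integrators against closed forms, cross-integrator agreement,
# refinement, determinism, and gating invariants.

passive_net <- function(E_rest = -60) {
  network_spec(list(
    neuron_spec("P", "MN", params = neuron_params(C = 5, G_leak = 1,
                                                  E_rest = E_rest))))
}

osc_params <- default_parameter_table()

test_that("initial state puts neurons at rest with gates at steady state", {
  net <- build_rhythm_generator("left", osc_params)
  st <- initial_state(net)
  rg <- net$neurons[["L_limb_RG_EXT"]]$params
  expect_equal(st$V, vapply(net$neurons, function(n) n$params$E_rest,
                            numeric(1)), ignore_attr = TRUE)
  i <- match("L_limb_RG_EXT", st$name)
  expect_equal(st$m[i], gating_steady_state(rg$E_rest, rg$m_gate))
  expect_equal(st$h[i], gating_steady_state(rg$E_rest, rg$h_gate))
  expect_equal(st$m[match("L_limb_IN_EXT", st$name)], 0)
})

test_that("a passive neuron's step response matches the closed form", {
  net <- passive_net()
  stim <- stimulus_protocol("P", 2, 0, 1)
  for (integ in c("exponential_euler", "rk4")) {
    tr <- run_simulation(net, stim,
                         config = simulation_config(dt = 0.1, duration = 0.05,
                                                    integrator = integ))
    # V(t) = E_rest + (I/G)(1 - exp(-t G / C)); frozen value at t = 10 ms
    closed <- -60 + 2 * (1 - exp(-tr$time * 1000 / 5))
    expect_lt(max(abs(tr$V[, "P"] - closed)), 1e-3)
    i10 <- which.min(abs(tr$time - 0.010))
    expect_equal(unname(tr$V[i10, "P"]), -58.27067056647323,
                 tolerance = 1e-6)
  }
})

test_that("simulations are deterministic and noise is seed-reproducible", {
  net <- build_rhythm_generator("left", osc_params)
  cfg <- simulation_config(duration = 0.5)
  kick <- startup_kick(net)
  a <- run_simulation(net, kick, config = cfg)
  b <- run_simulation(net, kick, config = cfg)
  expect_identical(a$V, b$V)
  nz <- noise_spec("L_limb_RG_EXT", sd = 0.5, seed = 11)
  n1 <- run_simulation(net, kick, noise = nz, config = cfg)
  n2 <- run_simulation(net, kick, noise = nz, config = cfg)
  expect_identical(n1$V, n2$V)
  n3 <- run_simulation(net, kick, noise = noise_spec("L_limb_RG_EXT", 0.5, 12),
                       config = cfg)
  expect_false(identical(n1$V, n3$V))
  # zero-amplitude stimulus leaves the trajectory untouched
  z <- run_simulation(net, list(kick, stimulus_protocol("L_limb_RG_FLX", 0,
                                                        0.1, 0.3)),
                      config = cfg)
  expect_identical(a$V, z$V)
})

test_that("gates stay in [0,1] at every recorded step", {
  net <- build_two_layer_cpg("left", osc_params)
  tr <- run_simulation(net, startup_kick(net),
                       config = simulation_config(duration = 2))
  expect_true(all(tr$m >= 0 & tr$m <= 1))
  expect_true(all(tr$h >= 0 & tr$h <= 1))
})

test_that("a symmetric half-center stays symmetric until perturbed", {
  # drop the default table's flexor excitability bias to get a truly
  # bilaterally symmetric pair
  sym <- osc_params
  sym$neurons$RG_osc_FLX <- NULL
  net <- build_rhythm_generator("left", sym)
  tr <- run_simulation(net, config = simulation_config(duration = 1.5))
  expect_lt(max(abs(tr$V[, "L_limb_RG_EXT"] - tr$V[, "L_limb_RG_FLX"])), 1e-9)
  kicked <- run_simulation(net, startup_kick(net),
                           config = simulation_config(duration = 1.5))
  expect_gt(max(abs(kicked$V[, "L_limb_RG_EXT"] -
                    kicked$V[, "L_limb_RG_FLX"])), 1)
})

test_that("halving dt barely changes limit-cycle voltages", {
  # refinement is measured on the limit cycle: the cold-start escape after
  # the kick is a grazing event whose timing dominates refinement error
  net <- build_rhythm_generator("left", osc_params)
  pre <- run_simulation(net, startup_kick(net),
                        config = simulation_config(duration = 2,
                                                   record_every = 10))
  init <- final_state(pre)
  a <- run_simulation(net, config = simulation_config(
    dt = 0.005, duration = 1, record_every = 20), init = init)
  b <- run_simulation(net, config = simulation_config(
    dt = 0.0025, duration = 1, record_every = 40), init = init)
  expect_equal(dim(a$V), dim(b$V))
  expect_lt(max(abs(a$V - b$V)), 0.1)
})

test_that("rk4 and exponential Euler agree within 0.5 mV at dt = 0.01 ms", {
  net <- build_rhythm_generator("left", osc_params)
  pre <- run_simulation(net, startup_kick(net),
                        config = simulation_config(duration = 2,
                                                   record_every = 10))
  init <- final_state(pre)
  ee <- run_simulation(net, config = simulation_config(dt = 0.01,
          duration = 1, record_every = 10), init = init)
  rk <- run_simulation(net, config = simulation_config(dt = 0.01,
          duration = 1, integrator = "rk4", record_every = 10), init = init)
  expect_lt(max(abs(ee$V - rk$V)), 0.5)
})

test_that("rk4 converges at fourth order on a smooth single neuron", {
  # persistent-sodium neuron relaxing from a displaced state: smooth flow
  p <- osc_params$neurons$RG_osc
  net <- network_spec(list(neuron_spec("N", "RG", params = p)))
  init <- initial_state(net)
  init$V <- -55; init$m <- 0.2; init$h <- 0.6
  vend <- function(dt) {
    tr <- run_simulation(net, config = simulation_config(
      dt = dt, duration = 0.02, integrator = "rk4",
      record_every = round(20 / dt)), init = init)
    tr$V[nrow(tr$V), 1]
  }
  ref <- vend(0.025)   # dt/16 reference
  e1 <- abs(vend(0.4) - ref)
  e2 <- abs(vend(0.2) - ref)
  order <- log2(e1 / e2)
  expect_gt(order, 3.5)
})

test_that("time-invariance: shifting a stimulus shifts the response exactly", {
  # exact property needs the pre-stimulus state to be an equilibrium; a
  # passive neuron at rest is one (the half-center is not: its symmetric
  # mode keeps evolving, so its phase depends on absolute kick time)
  net <- passive_net()
  delta <- 0.4
  a <- run_simulation(net, stimulus_protocol("P", 2, 0.1, 0.3),
                      config = simulation_config(duration = 1))
  b <- run_simulation(net, stimulus_protocol("P", 2, 0.1 + delta,
                                             0.3 + delta),
                      config = simulation_config(duration = 1.4))
  ca <- find_rising_crossings(a$time, a$V[, "P"], -59, hysteresis = 0)
  cb <- find_rising_crossings(b$time, b$V[, "P"], -59, hysteresis = 0)
  expect_equal(length(ca), length(cb))
  expect_equal(cb - delta, ca, tolerance = 1e-9)
})

test_that("startup kick targets the requested side and amplitude", {
  net <- build_rhythm_generator("right", osc_params)
  k <- startup_kick(net, "right")
  expect_equal(k$target, "R_limb_RG_EXT")
  expect_equal(k$amplitude, 2)
  expect_equal(c(k$t_on, k$t_off), c(0, 0.5))
  expect_error(startup_kick(net, "left"), "no rhythm-generator")
})

test_that("divergence is detected and attributed", {
  # absurd parameters that blow up: huge sodium conductance, no leak room
  p <- neuron_params(C = 0.001, G_leak = 0.001, E_rest = -60, G_Na = 1e3,
                     E_Na = 50,
                     m_gate = gating_params(1, -0.5, -55, 0.01),
                     h_gate = gating_params(1, -0.5, -55, 1e5))
  net <- network_spec(list(neuron_spec("BAD", "RG", params = p)))
  cfg <- simulation_config(dt = 0.5, duration = 0.2, integrator = "rk4")
  expect_error(
    run_simulation(net, stimulus_protocol("BAD", 50, 0, 0.2), config = cfg),
    "diverged")
})
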