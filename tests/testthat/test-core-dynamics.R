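# Pure neuron/synapse evaluation functions against closed forms and
# independently computed values.

test_that("gating steady state matches the sigmoid closed form", {
  g <- gating_params(A = 1, S = 0.3, E_half = -50, tau = 100)
  # V = E_half with A = 1 forces exp(0) = 1, hence 1/2, for any slope
  expect_equal(gating_steady_state(-50, g), 0.5)
  expect_equal(gating_steady_state(-50, gating_params(1, -2, -50, 1)), 0.5)
  # sigmoid limits for S > 0
  expect_lt(gating_steady_state(1e3, g), 1e-10)
  expect_gt(gating_steady_state(-1e3, g), 1 - 1e-10)
  # frozen value from an independent arbitrary-precision evaluation of
  # 1 / (1 + 0.5 * exp(-0.046 * -20))
  g2 <- gating_params(A = 0.5, S = -0.046, E_half = -40, tau = 50)
  expect_equal(gating_steady_state(-60, g2), 0.4435287655156433,
               tolerance = 1e-14)
  # strictly inside (0,1) and monotone decreasing for S > 0
  v <- seq(-120, 40, by = 0.5)
  z <- gating_steady_state(v, g)
  expect_true(all(z > 0 & z < 1))
  expect_true(all(diff(z) < 0))
})

test_that("gating derivative is first-order relaxation and rejects bad tau", {
  expect_equal(gating_derivative(0.3, 0.3, 17), 0)
  expect_equal(gating_derivative(0, 1, 2), 0.5)
  expect_error(gating_derivative(0.5, 0.5, 0), "tau")
  expect_error(gating_derivative(0.5, 0.5, -3), "tau")
  expect_error(gating_params(1, 0.1, -50, tau = 0))
})

test_that("an isolated gate relaxes exponentially with time constant tau", {
  g <- gating_params(A = 1, S = 0.25, E_half = -50, tau = 40)
  z_inf <- gating_steady_state(-60, g)
  # forward Euler at fine dt against the closed form z(t)
  dt <- 0.005
  t_end <- 200
  z <- 0.1
  for (i in seq_len(t_end / dt))
    z <- z + dt * gating_derivative(z, z_inf, g$tau)
  closed <- z_inf + (0.1 - z_inf) * exp(-t_end / g$tau)
  expect_equal(z, closed, tolerance = 1e-5)
})

test_that("graded synaptic conductance is piecewise linear, continuous, bounded", {
  s <- synapse_params(g_max = 0.6, E_syn = -10, E_lo = -60, E_hi = -40)
  expect_equal(synaptic_conductance(-70, s), 0)
  expect_equal(synaptic_conductance(-50, s), 0.3)   # ramp midpoint
  expect_equal(synaptic_conductance(-35, s), 0.6)   # saturation
  # continuity at the corners
  eps <- 1e-9
  expect_equal(synaptic_conductance(-60 - eps, s),
               synaptic_conductance(-60 + eps, s), tolerance = 1e-6)
  expect_equal(synaptic_conductance(-40 - eps, s),
               synaptic_conductance(-40 + eps, s), tolerance = 1e-6)
  # non-decreasing and bounded over a sweep
  v <- seq(-100, 20, by = 0.1)
  gsy <- synaptic_conductance(v, s)
  expect_true(all(diff(gsy) >= 0))
  expect_true(all(gsy >= 0 & gsy <= s$g_max))
  # degenerate ramp rejected at construction
  expect_error(synapse_params(0.1, -10, -50, -50), "E_lo")
})

test_that("membrane derivative matches term-by-term evaluation", {
  mg <- gating_params(1, -0.2, -40, 2)
  hg <- gating_params(1, 0.5, -52, 300)
  p <- neuron_params(C = 5, G_leak = 1, E_rest = -60, G_Na = 1.5, E_Na = 50,
                     m_gate = mg, h_gate = hg)
  # rest equilibrium for a passive cell
  pp <- neuron_params(C = 1, G_leak = 1, E_rest = -60)
  expect_equal(membrane_derivative(neuron_state(-60), pp), 0)
  # single-term arithmetic: C=1, G=1, Erest=-60, V=-50 -> -10 mV/ms
  expect_equal(membrane_derivative(neuron_state(-50), pp), -10)
  # full right-hand side with one active synapse and sodium current
  st <- neuron_state(V = -48, m = 0.4, h = 0.6)
  got <- membrane_derivative(st, p, syn_inputs = list(c(0.25, -70)),
                             I_app = 1.5)
  leak <- 1 * (-60 - -48)
  syn <- 0.25 * (-70 - -48)
  na <- 1.5 * (50 - -48) * 0.4 * 0.6
  expect_equal(got, (leak + syn + na + 1.5) / 5)
  # linear in applied current with slope 1/C
  d0 <- membrane_derivative(st, p, I_app = 0)
  d3 <- membrane_derivative(st, p, I_app = 3)
  expect_equal(d3 - d0, 3 / 5)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(neuron_params(C = 0, G_leak = 1, E_rest = -60))
  expect_error(neuron_params(C = 5, G_leak = 1, E_rest = -60, G_Na = 1),
               "gating_params")
  expect_error(neuron_params(5, 1, -60, m_gate = gating_params(1, 1, -40, 1)),
               "zeroed")
  expect_error(neuron_state(-60, m = 1.4), "m")
  expect_error(gating_params(A = -1, S = 0.1, E_half = -50, tau = 10))
})
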