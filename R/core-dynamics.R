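#' @useDynLib snscpg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm median setNames
#' @importFrom utils modifyList write.table read.table
NULL

# ---- parameter containers --------------------------------------------------
#
# Unit system fixed throughout the package: mV / ms / nA / uS / nF.
# With these units conductance*voltage is current (uS*mV = nA) and
# current/capacitance is a voltage rate (nA/nF = mV/ms), so the membrane
# equation needs no conversion factors.

#' Voltage-dependent gating parameters
#'
#' Parameters of the sigmoidal steady-state curve and first-order kinetics of
#' a persistent-sodium gating variable (activation `m` or inactivation `h`):
#' `z_inf(V) = 1 / (1 + A * exp(S * (V - E_half)))`, `dz/dt = (z_inf - z)/tau`.
#'
#' @param A dimensionless sigmoid factor (>= 0)
#' @param S slope, 1/mV; positive `S` gives a curve decreasing in V
#'   (inactivation-like), negative `S` increasing (activation-like)
#' @param E_half reference voltage, mV
#' @param tau time constant, ms (> 0)
#' @return an object of class `gating_params`
#' @export
gating_params <- function(A, S, E_half, tau) {
  stopifnot(is.numeric(A), length(A) == 1L, A >= 0,
            is.numeric(S), length(S) == 1L,
            is.numeric(E_half), length(E_half) == 1L,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(A = A, S = S, E_half = E_half, tau = tau),
            class = "gating_params")
}

#' Membrane parameters of a non-spiking leaky-integrator neuron
#'
#' Neurons obey
#' `C dV/dt = G_leak (E_rest - V) + sum G_syn (E_syn - V) +
#'  G_Na (E_Na - V) m h + I_app`.
#' Interneurons and other passive cells are the same type with `G_Na = 0`
#' and no gate dynamics.
#'
#' @param C membrane capacitance, nF (> 0)
#' @param G_leak leak conductance, uS (> 0)
#' @param E_rest resting potential, mV
#' @param G_Na persistent sodium maximal conductance, uS (>= 0)
#' @param E_Na sodium reversal potential, mV
#' @param m_gate,h_gate [gating_params()] for activation/inactivation;
#'   required iff `G_Na > 0`
#' @return an object of class `neuron_params`
#' @export
neuron_params <- function(C, G_leak, E_rest, G_Na = 0, E_Na = 50,
                          m_gate = NULL, h_gate = NULL) {
  stopifnot(is.numeric(C), C > 0, is.numeric(G_leak), G_leak > 0,
            is.numeric(E_rest), is.numeric(G_Na), G_Na >= 0,
            is.numeric(E_Na))
  if (G_Na > 0) {
    if (!inherits(m_gate, "gating_params") || !inherits(h_gate, "gating_params"))
      stop("neurons with G_Na > 0 need m_gate and h_gate gating_params")
  } else {
    if (!is.null(m_gate) || !is.null(h_gate))
      stop("passive neurons (G_Na = 0) must have zeroed gates")
  }
  structure(list(C = C, G_leak = G_leak, E_rest = E_rest, G_Na = G_Na,
                 E_Na = E_Na, m_gate = m_gate, h_gate = h_gate),
            class = "neuron_params")
}

#' Graded synapse parameters
#'
#' Conductance is a piecewise-linear function of the presynaptic voltage:
#' zero below `E_lo`, `g_max` above `E_hi`, and a linear ramp between.
#'
#' @param g_max maximal conductance, uS (>= 0)
#' @param E_syn synaptic reversal potential, mV
#' @param E_lo,E_hi lower/upper presynaptic thresholds, mV; `E_lo < E_hi`
#'   strictly (a degenerate ramp is rejected)
#' @return an object of class `synapse_params`
#' @export
synapse_params <- function(g_max, E_syn, E_lo, E_hi) {
  stopifnot(is.numeric(g_max), g_max >= 0, is.numeric(E_syn),
            is.numeric(E_lo), is.numeric(E_hi))
  if (!(E_lo < E_hi)) stop("synapse_params: E_lo must be strictly below E_hi")
  structure(list(g_max = g_max, E_syn = E_syn, E_lo = E_lo, E_hi = E_hi),
            class = "synapse_params")
}

#' Instantaneous state of one neuron
#'
#' @param V membrane voltage, mV
#' @param m,h sodium activation/inactivation, fractions in `[0, 1]`
#' @return an object of class `neuron_state`
#' @export
neuron_state <- function(V, m = 0, h = 0) {
  stopifnot(is.numeric(V), m >= 0, m <= 1, h >= 0, h <= 1)
  structure(list(V = V, m = m, h = h), class = "neuron_state")
}

# ---- pure evaluation functions ---------------------------------------------

#' Steady-state value of a gating variable
#'
#' Evaluates `1 / (1 + A * exp(S * (V - E_half)))`.
#'
#' @param V membrane voltage, mV (vectorised)
#' @param gate a [gating_params()] object
#' @return steady-state fraction(s); strictly inside (0, 1) when `A > 0`
#' @export
gating_steady_state <- function(V, gate) {
  stopifnot(inherits(gate, "gating_params"))
  1 / (1 + gate$A * exp(gate$S * (V - gate$E_half)))
}

#' First-order relaxation rate of a gating variable
#'
#' @param z current value, fraction
#' @param z_inf steady-state value, fraction
#' @param tau time constant, ms (> 0)
#' @return rate dz/dt in 1/ms
#' @export
gating_derivative <- function(z, z_inf, tau) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be positive")
  (z_inf - z) / tau
}

#' Graded synaptic conductance
#'
#' Piecewise-linear in the presynaptic voltage: 0 below `E_lo`, a linear ramp
#' to `g_max` at `E_hi`, saturated above.  Continuous and non-decreasing.
#'
#' @param V_pre presynaptic voltage, mV (vectorised)
#' @param syn a [synapse_params()] object
#' @return conductance, uS, in `[0, g_max]`
#' @export
synaptic_conductance <- function(V_pre, syn) {
  stopifnot(inherits(syn, "synapse_params"))
  frac <- (V_pre - syn$E_lo) / (syn$E_hi - syn$E_lo)
  syn$g_max * pmin(pmax(frac, 0), 1)
}

#' Membrane voltage derivative
#'
#' Right-hand side of the membrane equation, including an applied current
#' term inside the bracket (standard current-clamp convention):
#' `dV/dt = [G_leak (E_rest - V) + sum g_i (E_syn_i - V) +
#'   G_Na (E_Na - V) m h + I_app] / C`.
#'
#' @param state a [neuron_state()]
#' @param params a [neuron_params()]
#' @param syn_inputs list of `c(g, E_syn)` pairs (conductance uS, reversal mV)
#' @param I_app applied current, nA
#' @return rate dV/dt in mV/ms
#' @export
membrane_derivative <- function(state, params, syn_inputs = list(), I_app = 0) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "neuron_params"))
  i_syn <- 0
  for (s in syn_inputs) i_syn <- i_syn + s[[1]] * (s[[2]] - state$V)
  i_na <- params$G_Na * (params$E_Na - state$V) * state$m * state$h
  (params$G_leak * (params$E_rest - state$V) + i_syn + i_na + I_app) / params$C
}
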