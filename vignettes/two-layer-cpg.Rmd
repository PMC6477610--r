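---
title: "A two-layer locomotor CPG of non-spiking neurons: model, calibration, and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer locomotor CPG of non-spiking neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snscpg)
```

## The model

`snscpg` simulates small synthetic nervous systems: networks of
non-spiking leaky-integrator neurons in which each cell stands for a
population of spiking neurons, and synaptic transmission is graded rather
than spike-triggered.  A neuron's state is its membrane voltage $V$ (mV)
and, for rhythmogenic cells, a persistent-sodium channel with activation
$m$ and inactivation $h$:

$$C\,\dot V = G_\ell(E_\mathrm{rest}-V) + \sum_i G_{\mathrm{syn},i}(E_{\mathrm{syn},i}-V)
  + G_\mathrm{Na}(E_\mathrm{Na}-V)\,m\,h + I_\mathrm{app},$$
$$\dot z = (z_\infty(V) - z)/\tau_z,\qquad
  z_\infty(V) = \frac{1}{1 + A_z\exp\!\big(S_z (V-E_z)\big)},\qquad z\in\{m,h\},$$

with the graded synapse

$$G_\mathrm{syn}(V_\mathrm{pre}) =
  \begin{cases} 0 & V_\mathrm{pre} < E_\mathrm{lo}\\
  g_\mathrm{syn}\,\dfrac{V_\mathrm{pre}-E_\mathrm{lo}}{E_\mathrm{hi}-E_\mathrm{lo}} & E_\mathrm{lo} \le V_\mathrm{pre} \le E_\mathrm{hi}\\
  g_\mathrm{syn} & V_\mathrm{pre} > E_\mathrm{hi}.\end{cases}$$

Interneurons, motoneurons and Renshaw cells are the same cell type with
$G_\mathrm{Na}=0$ and no gate dynamics.  The printed membrane equation has
no applied-current term; `I_app` is added inside the bracket before
dividing by $C$ — the standard current-clamp convention, without which
current-pulse protocols in nA would be meaningless.  The unit system is
fixed throughout (mV, ms, nA, µS, nF) so the equation balances without
conversion factors; configuration files must declare these units.

The central circuit is a two-layer central pattern generator (CPG):

* a **rhythm generator** (RG) — a four-neuron half-center oscillator (two
  persistent-sodium cells coupled by weak mutual excitation and by
  reciprocal inhibition through one passive interneuron per direction) —
  keeps step-cycle time;
* **pattern formation** (PF) groups — one per hip, one shared by knee and
  ankle (the knee–ankle synergy) — reshape that timing into
  extensor/flexor activation envelopes; and
* a **motoneuron layer** with Renshaw-cell recurrent inhibition drives the
  (virtual) muscles.

RG→PF drive is excitatory extensor-to-extensor and flexor-to-flexor, with
crossed inhibition onto the opposite PF cell.  A one-layer baseline
circuit (half-center synapsing directly onto motoneurons) is also provided
to demonstrate why the second layer is needed: without it, any
perturbation moves step timing and motoneuron amplitude together.

## Parameter provenance and calibration

The packaged default parameter table
(`inst/extdata/default_params.yaml`) is a **synthetic transcription**: the
numerical parameter listing of the source network was not available, so
the defaults were calibrated, once, so that the assembled networks
reproduce the published behaviours of this circuit family:

* baseline stride period near 0.5 s (rising −60 mV crossings of the PF
  extensor);
* period shortened toward 0.35 s under +2 nA tonic drive to both RG
  cells, lengthened toward 0.65 s under −2 nA, returning to baseline when
  drive is removed;
* a brief excitatory PF stimulus reshapes only the ongoing cycle
  (extensor portion shortened, flexor prolonged) without moving later
  cycle onsets;
* a long excitatory PF stimulus suppresses rhythmic motoneuron bursting,
  which resumes on the expected clock (non-resetting);
* inhibiting the RG extensor resets the rhythm permanently, as does any
  perturbation of the one-layer baseline circuit.

Because the published stimulus windows (1.0–1.1 s and 2.0–2.1 s, with a
0–0.5 s startup kick) only produce these effects when they coincide with
the appropriate phase of the cycle, the calibration also fixed the
post-kick phase: the flexor RG cell is slightly less excitable than the
extensor (`RG_osc_FLX`, resting potential ≈1.3 mV lower), yielding the
extensor-dominant duty cycle characteristic of walking (stance longer
than swing) and placing the 2.0–2.1 s deletion window over the extensor
burst onset — where a −10 nA clamp blocks ignition and permanently
shifts the rhythm.  The calibrated oscillator stores its phase in the
slow inactivation variable h, so interruptions landing mid-burst are
re-absorbed within a cycle; only ignition-blocking perturbations reset
it.  A consequence, discussed under limitations, is that the short
pattern-formation stimulus of the memory protocol also overlaps a burst
onset in this alignment.  The single-layer baseline keeps a separate
parameter class (`HC_osc`) because its resetting demonstration relies on
accelerating the silent cell's escape, which requires the opposite phase
relation.

These choices were made once, against the published values, and are not
revisited per analysis.  Users who want to explore other regimes should
use the overlay mechanism (`load_parameter_table(path, overlay=)`) so
deltas stay separate from the calibrated base table.

## Numerical scheme

The integrator is fixed-step exponential Euler (conductances frozen over
a step; voltages and gates updated by their local exponential solutions),
with classical RK4 available for verification; both are compiled.  Per
step: external currents are assembled (stimulus + noise + afferents),
neurons advance, then the optional plant advances by semi-implicit Euler
from the just-updated motoneuron voltages.  Stimulus edges are aligned to
the step grid (onset floored, offset ceiled); sub-step edge placement is
irrelevant at the default resolution.  Gates are clamped against
numerical overshoot below 1e−9; larger gate excursions, non-finite
voltages, or |V| > 500 mV abort with the offending neuron and time.
Noise is white Gaussian current per step, scaled by $1/\sqrt{dt}$ so its
integrated variance is timestep-invariant, and every run's seed is
recorded in the trace provenance.

The persistent-sodium switching dynamics of the calibrated network are
stiff on the millisecond scale; the package default timestep is 0.01 ms.
Refinement behaviour is quoted on the limit cycle: starting from a
settled state, halving dt = 0.005 ms changes no limb-network voltage by
more than 0.1 mV over one second, and RK4 agrees with exponential Euler
to 0.22 mV at dt = 0.01 ms on the rhythm generator.  From a cold start
the escape that follows the startup kick is a grazing event whose timing
(and hence the voltage traces near switches) retains millisecond-scale
sensitivity to dt at any practical step size; cycle periods and all
classification outcomes are nevertheless stable from dt = 0.1 ms down.  The
rest state (`initial_state()`: every cell at `E_rest`, gates at their
steady state) is deliberately *not* an equilibrium of the full system —
the sodium current is small but nonzero at rest — which is why a
bilaterally symmetric model needs the documented 2 nA, 0.5 s startup kick
to the left RG extensor to break symmetry and start alternation.  (The
packaged table's flexor bias makes the default network self-starting,
but every canned protocol still applies the kick: it is part of the
protocol and sets the phase on which the stimulus windows land.)

## Measurement layer

Cycle detection finds rising threshold crossings (default −60 mV on the
PF extensor) by linear interpolation between bracketing samples, with a
refractory guard and a hysteresis re-arm (the signal must dip below
threshold − 0.5 mV before the next crossing counts) so that near-threshold
noise cannot double-count cycles.  Periods are successive crossing
differences; windowed means use only periods whose defining crossings both
lie inside the window.

Resetting is classified by comparing a perturbed run against a reference
run that shares every setting except the perturbation.  The reference
clock (pre-window mean period; the whole reference train when the window
opens before two cycles have elapsed) predicts post-window crossings; the
phase shift is the circular distance between predicted and observed
crossings in period fractions, so a whole-cycle slip counts as zero —
matching the "reappears at the expected time" semantics of non-resetting
deletions.  The steady-state shift (mean over the last three crossings)
is compared with a tolerance of 5% of a period: the source literature
gives no number; 5% separates the qualitative categories cleanly here and
is exposed as an argument.  Motoneuron bursts are intervals at or above
threshold; onset gaps exceeding 1.5× the median onset interval flag
deletions.

## The stand-in plant

The closed-loop module is deliberately *not* a biomechanical limb: one
rotational degree of freedom per PF group (hip; knee–ankle lumped), muscle
activation as a first-order low-pass of a saturating linear map of
motoneuron voltage, torque proportional to the activation difference with
viscous damping and a soft centering spring, and linear clamped afferent
currents (Ia-like ∝ angular velocity, II-like ∝ excursion, Ib-like ∝
extensor torque) routed onto the RG/PF targets reported for locomotor
feedback.  All of its equations are stand-ins whose only job is to close
the sensory loop plausibly; with all gains zero the loop is exactly
decoupled and reproduces the open-loop traces bit for bit.  It exists so
the qualitative closed-loop observation — that post-deletion rhythm
recovery is slowed by feedback rather than immediate — can be
demonstrated and explored.  Whether slow recovery in a full neuromechanical
model stems from sensory feedback or from mechanical entrainment through
the contralateral limb is an open question this module cannot settle.

## What the tests do and do not show

The test suite verifies the dynamics against closed forms (passive step
responses, gate relaxation), cross-checks the two integrators, checks
refinement behaviour, and reruns the canned experiments end to end.  All
of this operates on the synthetic calibrated network: passing tests show
the implementation is faithful to the stated model and that the
calibrated circuit reproduces the published phenomenology; they do not
show that the parameter values match the original network's, nor anything
about biological rats.  Known limitations: no spiking, one channel type,
no biomechanical body, no interlimb neural circuitry (the two limbs are
fully independent by construction), and afferent functional forms that
are linear stand-ins.  One published detail of the short-stimulus memory
protocol is not reproduced by this calibration: with the stride period at
0.5 s, the 1.0–1.1 s and 2.0–2.1 s windows fall at the same cycle phase,
and the phase that makes rhythm-generator inhibition resetting places the
short PF stimulus over the PF burst onset rather than inside the burst.
The stimulus then advances that onset, so the ongoing extensor portion
lengthens instead of shortening (the flexor prolongation and the
unchanged subsequent onsets are reproduced).  The corresponding
expectation in the acceptance tests is deliberately left failing rather
than re-specified.
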