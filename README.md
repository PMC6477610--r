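# snscpg — two-layer locomotor CPG networks of non-spiking neurons

`snscpg` simulates small synthetic nervous systems for locomotor rhythm
generation: networks of non-spiking leaky-integrator neurons with a
persistent sodium current and graded (piecewise-linear) synapses,
organised as a **two-layer central pattern generator** — a half-center
**rhythm generator** (RG) that keeps step-cycle time, **pattern
formation** (PF) groups that distribute the rhythm to the muscles
(including a shared knee–ankle synergy group), and a motoneuron/Renshaw
output layer.  It is aimed at computational neuroscientists and roboticists
studying how a layered CPG separates the control of step *timing* from
motoneuron *amplitude* — in particular resetting vs **non-resetting
deletions**: perturbations of the PF layer silence motoneuron bursts that
later reappear exactly on the clock kept by the RG, whereas perturbations
of the RG (or of a one-layer circuit) shift the rhythm permanently.

## Model

Each neuron obeys

```
C dV/dt = G_leak (E_rest − V) + Σ G_syn,i (E_syn,i − V)
          + G_Na (E_Na − V) · m · h + I_app
dz/dt   = (z_inf(V) − z) / τ_z ,  z_inf(V) = 1 / (1 + A_z exp(S_z (V − E_z))),
          z ∈ {m, h}
```

with graded synaptic conductance 0 below `E_lo`, `g_syn` above `E_hi`, and
a linear ramp between (units fixed: mV, ms, nA, µS, nF).  Interneurons,
motoneurons and Renshaw cells are the same cell type with `G_Na = 0`.
Integration is fixed-step exponential Euler (compiled; classical RK4 for
verification).  Cycle timing is read from rising −60 mV crossings of the
PF extensor; resetting is classified by the circular phase shift of
post-perturbation crossings against a reference run (non-resetting below
5% of a period).  A deliberately minimal one-degree-of-freedom plant per
PF group (with linear, clamped Ia/II/Ib-like afferent currents) closes
the sensory loop for qualitative demonstrations; with all gains zero it
reproduces the open-loop traces bit for bit.

The packaged parameter table is a calibrated synthetic transcription (the
original numerical listing was unavailable); see
`vignettes/two-layer-cpg.Rmd` for what was calibrated to what.

## Worked example

```r
library(snscpg)

net <- build_two_layer_cpg()        # RG + hip PF + motoneuron pair
res <- mlr_drive_experiment(net)    # startup kick; +2 nA 1.5-2.5 s and
                                    # -2 nA 3.5-4.5 s to both RG cells
print(res$epoch_table[res$epoch_table$neuron == "ext", ])
```

```
 neuron     epoch t_start t_end mean_period n
    ext  baseline     0.5   1.5          NA 0
    ext   excited     1.5   2.5   0.3622185 2
    ext  recovery     2.5   3.5   0.4979710 1
    ext inhibited     3.5   4.5   0.6229837 1
    ext     final     4.5   5.5   0.4986025 1
```

The tonic drive to both RG neurons shortens the stride period from about
0.5 s (measured over a longer unstimulated run; the 1 s baseline epoch
brackets only one crossing pair) to about 0.36 s; removing it restores
the baseline immediately; inhibitory drive lengthens the period toward
0.65 s.  The PF "memory"
experiment shows the two-layer separation of timing and amplitude:

```r
mem <- pf_memory_experiment(net)
mem$reset$long          # deleted motoneuron bursts, then non-resetting
mem$deleted_bursts      # >= 1 expected extensor burst absent (1 of 2)
deletion_experiment(build_limb(), layer = "RG")$reset$deletion
                        # inhibiting the RG extensor: resetting
```

A thin command line lives in `inst/cli/snscpg`
(`snscpg experiment drive --out DIR`, `snscpg run --network net.yaml ...`).

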