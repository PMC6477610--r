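# Default neuron and synapse parameter classes for the two-layer CPG
# networks.  SYNTHETIC transcription: these values were calibrated against
# the published network behaviours (baseline stride period and its
# modulation under descending drive, stimulus-window phasing, deletion
# phenomenology), not copied from a parameter listing; see the package
# vignette for the calibration account.  Unit system: mV / ms / nA / uS / nF.
units:
  voltage: mV
  time: ms
  current: nA
  conductance: uS
  capacitance: nF
neurons:
  RG_osc:
    C: 5.0
    G_leak: 1.0
    E_rest: -60.0
    G_Na: 2.3175
    E_Na: 50.0
    m: {A: 1.0, S: -0.22225, E: -44.262, tau: 2.0}
    h: {A: 1.0, S: 0.35469, E: -50.405, tau: 143.41}
  RG_osc_FLX:
    C: 5.0
    G_leak: 1.0
    E_rest: -61.3102
    G_Na: 2.3175
    E_Na: 50.0
    m: {A: 1.0, S: -0.22225, E: -44.262, tau: 2.0}
    h: {A: 1.0, S: 0.35469, E: -50.405, tau: 143.41}
  PF_osc:
    C: 4.0
    G_leak: 0.3
    E_rest: -61.346
    G_Na: 0.45
    E_Na: 50.0
    m: {A: 1.0, S: -0.26743, E: -47.83, tau: 2.0}
    h: {A: 1.0, S: 0.33579, E: -51.465, tau: 520.0}
  HC_osc:
    C: 5.0
    G_leak: 1.0
    E_rest: -60.0
    G_Na: 1.75
    E_Na: 50.0
    m: {A: 1.0, S: -0.23, E: -45.0, tau: 2.0}
    h: {A: 1.0, S: 0.45, E: -52.0, tau: 176.0}
  IN:
    C: 5.0
    G_leak: 1.0
    E_rest: -60.0
    G_Na: 0.0
    E_Na: 50.0
  MN:
    C: 5.0
    G_leak: 1.0
    E_rest: -65.0
    G_Na: 0.0
    E_Na: 50.0
  RE:
    C: 5.0
    G_leak: 1.0
    E_rest: -60.0
    G_Na: 0.0
    E_Na: 50.0
synapses:
  RG_mutual_excitation: {g_max: 0.019493, E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  RG_to_IN:             {g_max: 0.5,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  RG_IN_to_RG:          {g_max: 0.66365, E_syn: -70.0, E_lo: -60.0, E_hi: -40.0}
  RG_drive_PF:          {g_max: 0.055735, E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  RG_cross_inhibit_PF:  {g_max: 0.05, E_syn: -70.0, E_lo: -60.0, E_hi: -40.0}
  PF_to_IN:             {g_max: 0.5,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  PF_IN_to_PF:          {g_max: 0.1062, E_syn: -70.0, E_lo: -60.0, E_hi: -40.0}
  PF_to_MN:             {g_max: 1.0,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  MN_to_RE:             {g_max: 0.3,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  RE_to_MN:             {g_max: 0.1,  E_syn: -70.0, E_lo: -60.0, E_hi: -40.0}
  HC_mutual_excitation: {g_max: 0.02, E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  HC_to_IN:             {g_max: 0.5,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
  HC_IN_to_HC:          {g_max: 0.5,  E_syn: -70.0, E_lo: -60.0, E_hi: -40.0}
  HC_to_MN:             {g_max: 0.5,  E_syn: -10.0, E_lo: -60.0, E_hi: -40.0}
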