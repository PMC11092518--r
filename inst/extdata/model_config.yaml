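# Model configuration: neuron excitability tables, synaptic connection tables,
# receptor conventions and scale presets.
#
# Units are fixed package-wide: capacitance pF, voltage mV, current pA,
# conductance nS, time ms (so all table values are used verbatim).

populations:
  "MEC LII Stellate":
    count: 1600
    C: 118
    k: 0.62
    Vr: -58.53
    Vt: -43.52
    a: 0.005
    b: 11.69
    Vpeak: 11.48
    Vreset: -49.52
    d: 0
  "EC LI-II Multipolar Pyramidal":
    count: 1600
    C: 375
    k: 0.37
    Vr: -70.53
    Vt: -39.99
    a: 0.001
    b: 0.01
    Vpeak: 3.96
    Vreset: -54.95
    d: 7
  "CA1 Pyramidal":
    count: 1600
    C: 530
    k: 1.74
    Vr: -69.98
    Vt: -57.43
    a: 0.003
    b: -0.782
    Vpeak: 24.45
    Vreset: -60.35
    d: 25
  "EC LII AxoAxonic":
    count: 834
    C: 20
    k: 1
    Vr: -55
    Vt: -40
    a: 0.15
    b: 8
    Vpeak: 25
    Vreset: -55
    d: 200
  "MEC LII Basket":
    count: 833
    C: 20
    k: 1
    Vr: -55
    Vt: -40
    a: 0.15
    b: 8
    Vpeak: 25
    Vreset: -55
    d: 200
  "EC LII Basket Multipolar":
    count: 833
    C: 20
    k: 1
    Vr: -55
    Vt: -40
    a: 0.15
    b: 8
    Vpeak: 25
    Vreset: -55
    d: 200

# Short-term-plasticity synapse table.  g in nS, tau in ms, U unitless.
connections:
  "EC LI-II Multipolar Pyramidal to MEC LII Stellate":
    number: "1 to 1 +/- 0"
    g_fast: 11.627
    tau_d_fast: 3.380
    U: 0.180
    tau_u: 49.920
    tau_x: 152.856
    g_slow: 7.126
  "MEC LII Stellate to EC LII Axo-Axonic":
    number: "1 to 12 +/- 2"
    g_fast: 1.050
    tau_d_fast: 3.085
    U: 0.167
    tau_u: 49.920
    tau_x: 167.686
    g_slow: 0.644
  "MEC LII Stellate to MEC LII Basket":
    number: "1 to 12 +/- 2"
    g_fast: 1.050
    tau_d_fast: 2.887
    U: 0.167
    tau_u: 49.920
    tau_x: 152.857
    g_slow: 0.644
  "MEC LII Stellate to EC LII Basket Multipolar":
    number: "1 to 12 +/- 2"
    g_fast: 1.050
    tau_d_fast: 2.641
    U: 0.197
    tau_u: 49.920
    tau_x: 136.570
    g_slow: 0.644
  "EC LII Axo-Axonic to MEC LII Stellate":
    number: "1 to 142 +/- 66"
    g_fast: 0.626
    tau_d_fast: 4.561
    U: 0.145
    tau_u: 27.306
    tau_x: 420.838
    g_slow: 0.383
  "MEC LII Basket to MEC LII Stellate":
    number: "1 to 142 +/- 66"
    g_fast: 0.626
    tau_d_fast: 4.488
    U: 0.151
    tau_u: 27.810
    tau_x: 443.499
    g_slow: 0.383
  "EC LII Basket Multipolar to MEC LII Stellate":
    number: "1 to 142 +/- 66"
    g_fast: 0.626
    tau_d_fast: 4.948
    U: 0.162
    tau_u: 30.543
    tau_x: 382.485
    g_slow: 0.383
  "CA1 Pyramidal to MEC LII Stellate":
    number: "1 to 1 +/- 0"
    g_fast: 9.248
    tau_d_fast: 3.380
    U: 0.123
    tau_u: 49.710
    tau_x: 153.400
    g_slow: 5.668

# Receptor channel conventions (simulator-default style): reversal potentials,
# shared slow decay constant, and the voltage-dependent magnesium block applied
# to the slow excitatory (NMDA-like) channel.
receptors:
  E_fast_exc: 0.0     # AMPA-like reversal (mV)
  E_slow_exc: 0.0     # NMDA-like reversal (mV)
  E_fast_inh: -70.0   # GABA_A-like reversal (mV)
  E_slow_inh: -90.0   # GABA_B-like reversal (mV)
  tau_d_slow: 150.0   # shared slow-channel decay (ms)

# Arena geometry (cm)
arena:
  size: 45.0

# Conduction delay applied to every connection (ms)
delay_ms: 1.0

# Scale presets.  Geometry is in stellate-sheet units; phase_gain maps arena cm
# to sheet units (sheet units per cm) and therefore sets the grid scale in the
# arena.  Gain multipliers rescale table conductances per connection class at
# each simulated scale.
presets:
  intermediate:
    sheet_rows: 40
    sheet_cols: 40
    in_rows: 29
    in_cols: 29
    in_count: [834, 833, 833]
    annulus_inner: 3.0
    annulus_outer: 7.36
    disc_radius: 2.71
    xi: 2.0
    phase_gain: 0.32
    conj_I0: 165.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 6.0
    mult_in_sc: 6.0
    mult_in_sc_slow: 1.8
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0
  small:
    sheet_rows: 40
    sheet_cols: 40
    in_rows: 29
    in_cols: 29
    in_count: [834, 833, 833]
    annulus_inner: 3.0
    annulus_outer: 7.36
    disc_radius: 3.15
    xi: 2.0
    phase_gain: 0.28
    conj_I0: 165.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 4.5
    mult_in_sc: 6.0
    mult_in_sc_slow: 1.8
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0
  # Rate variants of the small scale: lower/higher conjunctive baseline
  small_low:
    sheet_rows: 40
    sheet_cols: 40
    in_rows: 29
    in_cols: 29
    in_count: [834, 833, 833]
    annulus_inner: 3.0
    annulus_outer: 7.36
    disc_radius: 3.15
    xi: 2.0
    phase_gain: 0.28
    conj_I0: 148.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 4.5
    mult_in_sc: 6.0
    mult_in_sc_slow: 1.8
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0
  small_high:
    sheet_rows: 40
    sheet_cols: 40
    in_rows: 29
    in_cols: 29
    in_count: [834, 833, 833]
    annulus_inner: 3.0
    annulus_outer: 7.36
    disc_radius: 3.15
    xi: 2.0
    phase_gain: 0.28
    conj_I0: 185.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 4.5
    mult_in_sc: 6.0
    mult_in_sc_slow: 1.8
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0
  large:
    sheet_rows: 40
    sheet_cols: 40
    in_rows: 35
    in_cols: 35
    in_count: [1200, 1200, 1200]
    annulus_inner: 4.5
    annulus_outer: 10.5
    disc_radius: 1.5
    xi: 2.6
    phase_gain: 0.26
    conj_I0: 165.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 20.0
    mult_in_sc: 2.1
    mult_in_sc_slow: 0.63
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0
  # Reduced bench-scale preset used for fast exploratory runs and sweeps:
  # quarter-size sheets with proportionally scaled interneuron counts and
  # center-surround geometry.
  desk:
    sheet_rows: 20
    sheet_cols: 20
    in_rows: 20
    in_cols: 20
    in_count: [400, 400, 400]
    annulus_inner: 2.5
    annulus_outer: 5.0
    disc_radius: 1.2
    xi: 1.0
    phase_gain: 0.30
    conj_I0: 165.0
    conj_alpha: 8.0
    conj_jitter: 2.0
    place_A: 260.0
    place_sigma: 5.0
    mult_conj_sc: 14.0
    mult_ca1_sc: 4.0
    mult_sc_in: 20.0
    mult_in_sc: 10.0
    mult_in_sc_slow: 3.0
    settle_ms: 500.0
    settle_pulse: 120.0
    settle_tau: 150.0

# Synthetic-foraging trajectory defaults
trajectory:
  rate_hz: 50.0
  mean_speed: 12.0
  heading_persistence: 0.9
  speed_cap: 90.0
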