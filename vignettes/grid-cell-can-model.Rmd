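---
title: "A spiking continuous-attractor model of entorhinal grid cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking continuous-attractor model of entorhinal grid cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`gridcan` simulates grid-cell activity in layer II of the medial entorhinal
cortex (MEC) as a spiking continuous attractor network (CAN). Six neuron
populations are modeled. Stellate cells (the grid cells) sit on a toroidal
40 x 40 neural sheet. They interact with each other *only* through
inhibition, relayed by three types of fast-spiking, parvalbumin-expressing
interneurons (axo-axonic, basket and basket-multipolar cells). Two
excitatory input streams drive the sheet: conjunctive (multipolar pyramidal)
cells carrying a speed- and direction-modulated velocity signal, and CA1
pyramidal place cells carrying a position signal used for drift correction.

## Neurons

Every neuron follows the nine-parameter Izhikevich formalism

$$C\dot v = k\,(v - V_r)(v - V_t) - u + I,\qquad
  \dot u = a\,[\,b\,(v - V_r) - u\,],$$

with the reset rule $v \ge V_{peak} \Rightarrow v \leftarrow V_{reset},\;
u \leftarrow u + d$. The per-population parameter rows ship in
`inst/extdata/model_config.yaml` in fixed units (pF, mV, pA, nS, ms), so the
published excitability constants are used verbatim: stellate cells are
low-gain integrators with strong sub-threshold adaptation ($b = 11.69$ nS,
$d = 0$), CA1 cells have a negative recovery coupling, and the three
interneuron types use a standard fast-spiking row ($a = 0.15$ /ms,
$d = 200$ pA).

Integration is forward Euler with `dt = 0.5` ms, the voltage advanced in two
half-steps per step for stability near spike onset. The rest state
$(V_r, 0)$ is an exact fixed point of the discrete update, and the test
suite checks a fine-step oracle (coarse vs. `dt = 0.001` ms within one spike
over a second of tonic drive).

## Synapses

Connections follow the Tsodyks-Markram (TM) short-term-plasticity model. At
each presynaptic spike the running release probability facilitates,
$u \leftarrow u + U(1-u)$, a fraction $R = u\,x$ of resources is released,
depressing $x \leftarrow x - R$, and two conductance channels are
incremented by $g_{fast} R$ and $g_{slow} R$. Between spikes $u$ decays to 0
with $\tau_u$, $x$ recovers to 1 with $\tau_x$, and conductances decay with
$\tau_{d}$; all four relaxations use exact exponentials (no Euler error).
Currents are ohmic, $I = \sum_c s_c (E_c - v)$, with reversal potentials
0 mV (fast and slow excitatory), -70 mV (fast inhibitory) and -90 mV (slow
inhibitory), and the slow excitatory (NMDA-like) channel is scaled by the
magnesium-block factor $((v+80)/60)^2 / (1 + ((v+80)/60)^2)$. The slow
decay constant is 150 ms for both slow channels. These are the standard
simulator-default conventions for the platform family the parameter tables
come from; the per-connection fast kinetics come from the packaged table.

The facilitation convention (decay to 0, increment $U(1-u)$) is the classic
1998 form; an alternative convention decays $u$ to $U$, which would make the
first-spike release identical but subsequent dynamics slightly different.

## Topology

All populations live on 2-D sheets with periodic (torus) boundary
conditions, expressed in the stellate sheet frame. Periodicity is the
standard choice for CAN bump stability; an aperiodic sheet would need
envelope functions that this model family does not use.

* Each stellate cell has one of four cardinal preferred directions,
  assigned by a deterministic 2 x 2 tiling (N, E / W, S), so each direction
  covers exactly a quarter of the sheet and sums to zero over every tile.
* Stellate to interneuron: each stellate excites the interneurons inside a
  small disc whose center is displaced by $\xi$ sheet units *along the
  cell's preferred direction*. The disc radius is set per scale preset so
  the mean out-degree matches the published connection counts (12 per
  interneuron type at the intermediate scale; more at smaller scales, fewer
  at larger ones, reproducing the dorsoventral connectivity trend).
* Interneuron to stellate: each interneuron inhibits every stellate in an
  annulus around its position (inner radius < outer radius), with uniform
  weights. The annulus radii are per-preset constants calibrated so the
  out-degree matches the published 142 +/- 66 at the intermediate scale.
* Conjunctive cells are index-matched one-to-one onto stellates (sharing
  their preferred direction); CA1 place cells project one edge each onto
  the stellate whose attractor phase corresponds to the cell's field center
  under the linear arena-to-sheet phase map (below).

The effective stellate-to-stellate interaction is therefore a displaced
center-surround inhibitory kernel — the classic recipe for a hexagonal
pattern of activity bumps on the sheet, with the displacement turning
velocity-biased drive into pattern translation.

## Drive

The conjunctive population receives the speed-control current
$$I_i = I_0 + \alpha\, s\, \tfrac{1}{2}\bigl(1 + \cos(h - \theta_i)\bigr),$$
where $s$ and $h$ are running speed and direction. Summed over the four
cardinal preferred directions the tuning factor is exactly 2, so total
network drive depends only on speed; its *distribution* across direction
classes is what moves the bumps. Place cells receive Gaussian field
currents $I_j = A\,\exp(-\|p - c_j\|^2 / 2\sigma^2)$ with $\sigma = 5$ cm
and centers tiling the arena on the stellate lattice.

Two forms of quenched heterogeneity are essential and are drawn once per
run from the seeded RNG: random initial membrane phases (uniform between
$V_r$ and $V_t$) and a small static jitter of the conjunctive baseline
(s.d. 2 pA). Without them, identically parameterized neurons receiving
identical input spike in lock-step and the network collapses into a global
synchronous oscillation instead of forming bumps.

## Position tracking: velocity drive plus place anchoring

The arena-to-sheet phase map `phase_gain` (sheet units per cm) fixes the
grid scale: the arena period of the pattern is the sheet lattice constant
divided by `phase_gain`. During calibration we measured the intrinsic
velocity-driven bump speed directly (regressing pattern displacement on
animal displacement with the place input disabled): with biologically
reasonable direction-modulation amplitudes it reaches only ~0.1-0.2 sheet
units/cm, below what the phase map requires. The place-cell input therefore
does most of the positional work, continuously dragging the anchored bump
to the phase of the animal's true position while lattice rigidity carries
the remaining bumps — consistent with the emphasis this model family places
on place-cell drift correction. The velocity pathway still biases motion in
the right direction (the offset sign was verified by the same displacement
regression) and the model's grid patterns degrade if it is removed together
with the anchor.

## Settling

Each run begins with a 500-ms settle phase: zero velocity, baseline
conjunctive drive, place input at the starting position, and a decaying,
heterogeneous excitation pulse to the stellate sheet that nucleates the
bump lattice. The settle phase is excluded from every analysis.

# Scale presets

Four presets ship in the configuration: `small` (with `small_low` /
`small_high` rate variants), `intermediate`, `large`, and a reduced `desk`
bench preset (20 x 20 stellate sheet) for fast runs and sweeps. The
full-scale presets use the published population counts (1600 stellate /
conjunctive / place cells; 834/833/833 interneurons per type, raised to
1200 each at the large scale). Per-preset constants — center-surround
radii, direction offset, phase gain, drive gains, and per-connection-class
conductance multipliers — were calibrated once so that (a) connection
counts match the published degree statistics, (b) stellate mean rates land
in the published low-single-digit spikes/s range, and (c) bumps track the
trajectory. The conductance multipliers play the role of the per-scale
gain adjustments the original tables mention but do not specify; the desk
preset additionally uses denser interneuron sheets (one interneuron per
stellate per type), because at 400 stellate cells the sampled annulus
otherwise becomes too granular to support a stable lattice.

The rate variants differ only in the conjunctive baseline current
(148 / 165 / 185 pA), which moves stellate mean rates between roughly 1.7
and 2.5 spikes/s without touching the attractor geometry.

# Synthetic foraging trajectories

`synthesize_trajectory()` emulates open-field random foraging in the
45 x 45 cm arena: a wrapped-Gaussian heading random walk (persistence 0.9),
a mean-reverting speed fluctuation clipped at zero, and reflective walls.
The default mean speed is 12 cm/s — an actively foraging rodent — chosen so
that 5-minute sessions already cover the arena densely enough for rate
maps; at 10+ minutes every 3-cm bin is visited. Speeds above 90 cm/s are
treated as outliers and clipped in the velocity signal. What the generator
does *not* emulate: wall-following and thigmotaxis, rest periods, goal
directed runs, and the heavy-tailed speed bursts of real mice. Tests passing
on synthetic sessions therefore show that the network tracks a plausible
velocity/position stream, not that it reproduces every statistic of real
locomotion.

# Analysis stack

* **Rate maps**: 3-cm bins, spike positions interpolated from the
  trajectory, counts and occupancy separately smoothed with a truncated
  Gaussian ($\sigma = 3$ cm) before division. Unvisited bins are flagged
  missing, never zero-filled (zero-imputation inflates grid scores).
* **Autocorrelograms**: Pearson correlation of the map with itself at every
  2-D lag over mutually visited bins; lags with fewer than 20 overlapping
  bins are masked.
* **Grid score**: annulus around the central peak (inner radius at the
  first zero crossing of the angularly averaged correlation; outer radius
  swept in one-bin steps to half the map, score maximized), with the
  rotation statistic min(r60, r120) - max(r30, r90, r150). Scores above
  0.2 mark an acceptable grid. On a square map the per-lag Pearson
  normalization leaves a faint fourfold-symmetric imprint, so radially
  symmetric *maps* score slightly negative rather than exactly zero; an
  ideal radially symmetric autocorrelogram scores ~0 as expected.
* **Fields**: connected components above 20% of the map peak, minimum area
  9 bins. Components containing several well-separated peaks are split at
  the watershed between them (bins assigned to the nearest peak; maxima
  closer than two bins merge). Without the split, neighboring grid fields
  joined by a suprathreshold ridge are measured as one merged region — at
  the large scale a single "field" spanning most of the arena — which is
  plainly wrong as a field-size method. Field size is the equivalent-circle
  diameter; a cell's size statistic is the mean over its fields.
* **Spacing/orientation**: median distance from the autocorrelogram center
  to the six nearest peripheral peaks; peaks are detected on a lightly
  smoothed copy with a 0.1 correlation floor, so structureless maps report
  no spacing instead of a spurious one. In the 45-cm arena the maximum
  measurable lag is ~42 cm, which caps measurable spacing below the
  published large-scale values — the same geometric cap applies to any
  recording in this arena.
* **Rhythms**: population rates in 1-ms bins; PSD by averaged sine-taper
  multitaper (5 tapers, 10-s segments) after 3-ms Gaussian pre-smoothing;
  band fractions over delta/theta/beta/gamma with total power normalized
  over 1-100 Hz. Spike-phase coupling band-passes the reference around its
  beta peak (2nd-order Butterworth, forward-backward), assigns phases by
  the analytic signal, and reports the mean resultant vector length with
  the large-sample Rayleigh test. Sine tapers are used instead of Slepian
  tapers: they are closed-form, orthonormal, and give equivalent variance
  reduction for smooth spectra.

# Parameter sweeps

`run_sweep()` reproduces the robustness analysis: nine values per
parameter (the base value centered), one simulation per grid cell with a
shared trajectory and seed, each scored on the probed central stellate.
Izhikevich sweeps modify the stellate population; TM sweeps modify the
three stellate-to-interneuron connections jointly. Biological-realism
bounds are shipped as editable per-parameter constants because the
firing-pattern fitness machinery that defined them requires experimental
traces that are not distributed with the model; the two-standard-deviation
rule can be applied directly to the TM tables. The reset voltage is
exposed under the aliases `Vreset`, `c` and `V_min`, since the robustness
literature uses all three names for the same column. Exhaustive 9 x 9
evaluation replaces evolutionary search: identical coverage,
deterministic, simpler.

# Problem sizes and numerical choices

Default analysis sessions are 5 simulated minutes (desk and full scale);
the multi-scale mixture (`run_scale_mixture()`) runs six 5-minute
experiments (two each of `small_low`, `small_high`, `large`) and pools 29
probed cells, mirroring the published 11 + 9 + 9 composition. One-minute
sessions feed the rhythm statistics, matching the first-minute convention.
The engine integrates at `dt = 0.5` ms with 1-ms conduction delays and
event-driven exact-exponential synapse updates; runs are bit-identical for
identical inputs and seeds.

# Known limitations

* Measured field sizes run ~30% above the published median at matched
  spacing: the uniform-weight annulus yields bumps whose width/spacing
  ratio (~0.4) exceeds that of real cells (~0.26). A graded center-surround
  weight profile would likely sharpen fields; the published profile is in
  supplementary material that is not available, and uniform weights are the
  minimal structure satisfying the printed degree statistics.
* The population rhythm peaks at ~11-13 Hz with a 25-40 Hz shoulder, so
  the beta band does not dominate the combined layer-II spectrum the way
  the published analysis reports (the conjunctive population alone does
  show beta dominance). The oscillation frequency is set by the same
  per-scale conductance rescalings that were calibrated once against the
  grid/rate targets and not revisited.
* Path integration is anchor-dominated: without place input the intrinsic
  velocity gain undershoots the phase map and grids degrade over minutes.
* Wilcoxon comparisons against real recordings require the recorded
  sessions and are out of scope.
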