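---
title: "A tile-partitioned spiking model of the cerebellar microcircuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tile-partitioned spiking model of the cerebellar microcircuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cbsim` simulates a layered-sheet model of one square millimeter of
cerebellar cortex together with its afferent nuclei. Seven anatomical layers
are stacked along depth — upper and lower molecular layers, the Purkinje-cell
layer, the granular layer, the deep cerebellar nucleus (DCN), the inferior
olive (IO) and the pons — with thicknesses 0.1, 0.1, 0.03, 0.2, 0.1, 0.1 and
0.2 mm. Each layer holds one or more square sheets of evenly spaced neurons;
per tile the model contains 4,096 stellate cells (ST, four sheets of 32 x 32),
1,024 each of basket (BA), Purkinje (PC), Golgi (GO), DCN and pons cells
(one 32 x 32 sheet each), 819,200 granule cells (GR, eight sheets of
320 x 320) and a single IO cell — 827,393 cerebellar neurons per tile, and
68,627,284,992 when the tile is replicated over a full 82,944-tile array.
The tile is the unit of parallel decomposition: tiles exchange spikes only
with their eight neighbors, which is what makes the sheet scalable.

Every neuron is a conductance-based leaky integrate-and-fire unit,

$$\tau_m \frac{dv}{dt} = -(v - E_{rest}) - \sum_r g_r(t)\,(v - E_r) + I_{ex} + I_{drive}(t),$$

stepped by forward Euler at a fixed $dt = 0.1$ ms. A spike is emitted when
$v \ge \theta$ after the Euler update, recorded at the step's end time; the
membrane then clamps at $v_{reset}$ for the absolute refractory period.
Membrane constants per population (time constant, threshold, reset, rest,
constant drive, refractory period) are the shipped defaults of
`cerebellar_tile_spec()`; notable rows are the granule cell
($\tau_m = 7.2$ ms, $\theta = -35$ mV, rest $-58$ mV) and the olivary cell
with its 1,500 ms refractory period, which pins its intrinsic rate near
0.66 Hz.

Synapses are alpha-function conductances. A spike arriving on a receptor with
time constant $\tau$ contributes $w\,(t/\tau)\,e^{1 - t/\tau}$: the waveform
is peak-normalized, so a table weight $w$ is the peak conductance a single
spike reaches at $t = \tau$ (in units of the leak conductance). AMPA and the
generic GABA$_A$ receptor use $\tau = 2$ ms, NMDA 100 ms, and the
Golgi-to-granule GABA$_A$ synapse 10 ms. The engine realizes the alpha kernel
as two coupled first-order stages advanced by their exact exponential
integrator, so the recurrence equals the closed form at grid times to machine
precision (the package tests assert this); a spike impulse adds $w\,e$ to the
driving stage. Every projection has a synaptic delay of exactly one Euler
step, including cross-tile projections — this is also what makes per-tile
scheduling bit-identical to single-partition stepping.

Wiring uses two kernel families. Radial projections (GO to GR, IO to PC, pons
to GR, and NRTP to GR in the OKR variant) connect each candidate pair at
planar distance $d$ independently with probability
$p\,e^{-d^2/(2\sigma^2)}$, cut off at $3\sigma$ (the neglected tail holds
less than 1.2% of the kernel mass). Parallel-fiber style projections use the
orthogonal-cross kernel: a uniform probability inside an axis-aligned
rectangle centered on the presynaptic cell, with mediolateral extent
$2 \cdot \mathrm{pre\_width}$ (the parallel-fiber beam, along x) and
rostrocaudal extent $\mathrm{post\_width}$. At most one synapse exists per
(pre, post, receptor) triple and self-edges are never drawn. Kernels are
planar: depth separations do not enter the distance.

## Parameters that are not printed anywhere

The parameter tables the model encodes give no leak conductance, no synaptic
reversal potentials, and no alpha normalization, so the absolute synaptic
gain is fixed here by documented conventions rather than by data:

* `i_ex` is interpreted as a steady depolarization in mV at unit leak
  conductance. This makes the constant-drive rows self-consistent: a Purkinje
  cell with $I_{ex} = 22$ and $\theta - E_{rest} = 20$ mV pacemakes at
  $1000/(1 + 10\ln 11) \approx 40$ Hz before synaptic input, a pons cell with
  $I_{ex} = 24$ at $\approx 53$ Hz (the "strong input" condition), the IO row
  at $\approx 0.66$ Hz.
* Reversal potentials default to 0 mV (AMPA, NMDA) and $-80$ mV (GABA$_A$).
* NMDA is a slow, voltage-independent alpha conductance; only its time
  constant is specified.
* GABA$_B$ appears in the circuit's pharmacology but has no printed
  parameters; the configuration parser rejects it.
* Transmitter type follows the presynaptic population: GR, pons, NRTP and IO
  are excitatory; ST, BA, PC and GO inhibitory.

These conventions are deliberate, fixed once, and exposed in the
configuration files; their consequences are discussed under *Limitations*.

## Protocols

`run_resting_state()` drives the pons sheet as independent 8 Hz Poisson
sources (Poisson emission replaces the pons membrane dynamics — no constant
drive reproduces a robust 8 Hz under the LIF equation) and measures
population-mean rates after a 500 ms warmup. `run_strong_input()` raises the
drive to 50 Hz; this is the condition in which granule cells express the
granular layer's reservoir property — irregular alternation between burst and
silent states, quantified by the similarity index below. The 50 Hz condition
defaults to Poisson emission rather than the intrinsic $I_{ex} = 24$
pacemaker: all pons cells start from the same state, so pacemaking would be
perfectly synchronous across the population and would impose an artificial
comb on the granular layer; the pacemaker remains available as
`pons_mode = "pacemaker"`.

`run_okr()` runs the optokinetic-response benchmark on the extended model
(`okr_tile_spec()`): a 32 x 32 NRTP sheet relays visual motion into granule
cells (Gaussian kernel, peak 0.1, $\sigma = 75\,\mu$m, weight 0.5 — the same
weight as the pons mossy input it parallels, with a comparable expected
in-degree of about four per granule cell), and a 32 x 32 vestibular-nucleus
sheet receives Purkinje inhibition through the PC-to-DCN geometry. VN
membranes reuse the DCN row with $I_{ex} = 40$; PC drive is raised to 24. The
stimulus is $I(t) = A\,(1 - \cos 2\pi t/T)/2$ with $T = 2$ s — one cycle per
2 s analysis window, non-negative, silent at the trough. $A = 18$ comes from
the closed-form LIF rate: it puts the NRTP peak near 30 Hz. The retinal-slip
pathway is deliberately absent: the IO keeps its intrinsic dynamics and there
is no plasticity, so no gain adaptation is modeled. The 8 Hz pons background
stays on during OKR. Two constants in this variant are calibrations, fixed
once and then frozen: $A$ (above) and the PC-to-VN weight (0.024), chosen so
that VN cells inhibited by Poisson PC trains at the measured 57.4 Hz PC
baseline settle near 35 Hz. The calibration touches only the baseline mean;
the modulation range the protocol produces is untouched validation output.

Experiments default to a periodic boundary: a single simulated tile then has
no wiring edge effects and behaves like an interior tile of a large array
(kernels wrap by minimal image; windows wider than the domain clamp to one
period). The open boundary, where kernels simply truncate, is the default for
raw `simulation_settings()`.

## Analysis

For a set of granule cells, `compute_z_traces()` forms the exponentially
filtered spike trains
$z_i(t) = \frac{1}{\tau_{PC}} \sum_{s \le t} e^{-(t-s)/\tau_{PC}} f_i(s)$
(with $\tau_{PC} = 50$ ms) via the per-step recurrence
$z \leftarrow z\,e^{-dt/\tau} + f_i(t)/\tau$; the tests pin the recurrence to
the brute-force sum below $10^{-9}$. `similarity_index()` is the
time-averaged cosine similarity between the population vectors $z(t)$ and
$z(t + \Delta t)$, averaged over a window of $T = 2$ s: 1 at lag zero, in
$[0, 1]$ always, and decaying with lag exactly when the active population
drifts. Grid points where either norm vanishes (before the first spike, for
example) are excluded from the average rather than counted as zero — the
quotient is undefined there — and their number is reported. The default lag
grid is 0–500 ms in 10 ms steps.

`rate_trace()` bins population rates (default 50 ms bins for OKR fitting) and
`cosine_fit()` fits $a + b\cos(2\pi f t + \varphi)$ by linear regression on
the cosine and sine components, with $b \ge 0$ by convention and the
modulation range reported as $[a - b, a + b]$, floored at zero. NRTP cells
are identical deterministic oscillators under a common drive, so their
population rate is a synchronized volley train; at fine bins this
quantization caps the cosine fit's variance explained, and the package's
tests fit NRTP at 250 ms bins (the rectified ideal waveform itself has an
asymptotic $R^2$ of about 0.86).

## Scheduling, halo exchange, and timing

The engine advances all tiles in one address space, sequentially within each
step: spike delivery walks the per-projection adjacency (attributed to
synapse time), the halo-exchange phase collects the border-region spikes each
neighbor tile would receive over a distributed transport (attributed to
communication time and validated against the halo map), and the per-tile
neuron phase advances filters and membranes (attributed to neuron time).
`n_workers` is recorded metadata: execution is sequential and results are
independent of it, as they are of the scheduler — `run_simulation()` produces
bit-identical spike output whether it steps tile-by-tile or per population,
which the tests assert. `run_scaling_benchmark()` replicates the same
per-tile load over growing tile counts and reports the per-bucket seconds;
the weak-scaling property at desk scale is that per-tile neuron and synapse
time stay flat.

## Numerical choices and degenerate inputs

* Double precision throughout; spike times recorded at 0.1 ms resolution.
* Threshold test after the Euler update; refractory neurons clamp at
  $v_{reset}$ and do not integrate, but their synaptic filters keep evolving.
* Initial state: $v = E_{rest}$, filters and refractory clocks at zero.
* Wiring randomness is a counter-based stream per (seed, projection, pre
  tile); Poisson drivers hash (seed, neuron, step). Adding tiles therefore
  never rewires existing tiles, and results never depend on scheduling.
* A non-finite membrane potential aborts the run with a diagnostic.
* Zero-length simulations return empty records; empty analysis windows and
  sub-cycle cosine fits are errors.

## What the density scaling does and does not preserve

`scale_tile_spec()` shrinks every sheet by $\sqrt{f}$ per axis and multiplies
the weights of projections whose presynaptic population shrank by the count
ratio, preserving the *expected* summed drive per postsynaptic cell (the
tests verify this to 5%). It does not preserve dynamics: fewer, stronger
inputs have larger variance, so reduced tiles burst harder, and beyond about
$f = 1/4$ single-event inhibitory conductances (notably GO to GR, weight 3
at full density) grow so large that the explicit Euler step leaves its
stability region ($dt\,(1 + \sum g)/\tau_m \gtrsim 2$), producing spurious
dynamics. For this reason the reservoir properties (burst/silent occupancy,
similarity-index decay) are validated on full-density runs, the
inhibition-sanity property is checked open-loop at printed-scale weights, and
reduced-density fixtures are used only for mechanical contracts (wiring
statistics, determinism, partition equivalence, protocol plumbing). At full
density the printed weights sit comfortably inside the stability region.

Problem sizes used by the shipped checks: the resting-state and OKR
benchmarks run one full-density tile (827k–829k neurons, about 38 million
synapses) for 2.5 s and 4.5 s of biological time; mechanical properties run
at 1/16 or 1/64 density for about a second each.

## Limitations

The absolute synaptic gain is under-determined by the printed parameters (no
leak conductance, reversal potentials or alpha normalization are given), and
the network's emergent rates are sensitive to it: under this package's
documented conventions a single mossy EPSP depolarizes a granule cell by
about 10 mV against a 23 mV threshold gap, so granule cells fire on triple
coincidences and the resting granular-layer rate sits near 0.5 Hz with
silent molecular-layer interneurons, whereas pacemaker-dominated populations
(PC, DCN) and the OKR Purkinje modulation range land close to the reference
values. A gain convention roughly 30–40% hotter would shift the granular
layer into the pair-coincidence regime those reference rates imply; the
package keeps the documented convention rather than tuning toward outputs.
Other deliberate omissions: no synaptic plasticity (hence no OKR gain
adaptation), no GABA$_B$, no retinal-slip drive to the IO, no conduction
delays beyond the single integration step, no sub-step spike interpolation,
and planar kernels (depth never enters connectivity).
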