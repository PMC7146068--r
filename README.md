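# cbsim — tile-based spiking simulation of the cerebellar microcircuit

`cbsim` builds and simulates layered-sheet models of the cerebellar
microcircuit at single-neuron resolution. One square millimeter of cerebellar
cortex — 827,393 conductance-based leaky integrate-and-fire neurons across
seven stacked layers, dominated by 819,200 granule cells — forms a *tile*;
tiles are replicated in the plane and exchange spikes only with their eight
neighbors, the decomposition that lets sheet models of this kind scale to
whole-brain sizes (82,944 tiles of this model contain 68,627,284,992
neurons, a human-scale cerebellum). The package is aimed at computational
neuroscientists who want a desk-scale, fully reproducible implementation of
this architecture: the declarative model description, the wiring kernels, the
fixed-step engine, the benchmark protocols and the spike-pattern analyses are
all exposed as ordinary R functions returning tibbles.

## The model in brief

* **Neurons.** Conductance-based LIF:
  `tau_m dv/dt = -(v - E_rest) - sum_r g_r (v - E_r) + I_ex + I_drive(t)`,
  forward Euler at dt = 0.1 ms, absolute refractoriness, spike at threshold
  crossing. Per-population constants ship with `cerebellar_tile_spec()`.
* **Synapses.** Peak-normalized alpha conductances
  `w (t/tau) exp(1 - t/tau)` (AMPA/GABA_A 2 ms, NMDA 100 ms, Golgi-to-granule
  GABA_A 10 ms), realized by an exact exponential-integrator recurrence, with
  a one-step synaptic delay everywhere.
* **Wiring.** Two-dimensional Gaussian kernels
  `p exp(-d^2 / (2 sigma^2))` for radial projections and orthogonal-cross
  rectangles (uniform `p` inside a `2*pre_width` by `post_width` box) for
  parallel-fiber projections; about 38 million synapses per full-density
  tile. Counter-based random streams per (seed, projection, tile) make the
  build bit-reproducible and partition-invariant.
* **Protocols.** Resting state (8 Hz Poisson mossy-fiber drive), constant
  strong drive (50 Hz; granule cells then show reservoir-like burst/silent
  alternation, quantified by a lagged population similarity index), and an
  optokinetic-response (OKR) benchmark with an NRTP relay driven by a
  non-negative sinusoid and a vestibular-nucleus output stage under Purkinje
  inhibition, summarized by cosine fits `a + b cos(2 pi f t + phi)`.

## A worked example

One full-density resting-state tile (about two minutes of compute, ~2 GB):

```r
library(cbsim)
ex <- run_resting_state(density = 1, duration = 2500, warmup = 500, seed = 1)
print(ex)
#> <cb_experiment: resting> 2500 ms (warmup 500), seed 1
#> # A tibble: 8 × 2
#>   population rate_hz
#>   <chr>        <dbl>
#> 1 ST           0
#> 2 BA           0
#> 3 PC          45.3
#> 4 GR           0.499
#> 5 GO           0
#> 6 DCN         30.9
#> 7 IO           0.5
#> 8 Pons         7.99
```

Reading: pons cells emit their prescribed 8 Hz Poisson mossy-fiber input;
Purkinje cells fire at 45 Hz (their intrinsic 40 Hz pacemaking plus granule
drive), the deep cerebellar nucleus at 31 Hz under Purkinje inhibition, the
olivary cell at its refractory-limited 0.5 Hz, and granule cells at 0.5 Hz —
under the package's documented gain conventions granule cells need about
three coincident mossy spikes to fire, which also leaves the molecular-layer
interneurons silent at rest (see the vignette's *Limitations* for why this
differs from the reference resting rates). Raw spikes and per-tile timing
ride along:

```r
head(ex$spikes, 3)
#> # A tibble: 3 × 3
#>    t_ms    gid population
#>   <dbl>  <int> <chr>
#> 1   0.2 827889 Pons
#> 2   0.4 827594 Pons
#> 3   0.6 828416 Pons
```

Smaller building blocks compose the same way:

```r
spec <- cerebellar_tile_spec()            # the full declarative model
validate_spec(spec)                       # -> 0-row tibble: valid
net  <- build_network(scale_tile_spec(spec, 1/16),
                      simulation_settings(1000, seed = 1,
                                          boundary = "periodic"))
sim  <- run_simulation(net, record = "GR")
```

and the analyses are plain functions over spike tables: `mean_firing_rate()`,
`rate_trace()` + `cosine_fit()` (with `tidy()`/`glance()` methods and
`autoplot()`), `compute_z_traces()` + `similarity_index()`,
`spike_raster_table()`. A thin command-line front end lives at
`inst/cli/cbsim.R` (`spec`, `run`, `scale`, `analyze` subcommands), and the
default model ships as JSON under `inst/extdata/`.

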