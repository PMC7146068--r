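#' Benchmark protocols
#'
#' Turnkey wrappers that build a (possibly density-reduced) tile model, run
#' it, and summarize the population activity:
#'
#' * `run_resting_state()` — spontaneous mossy-fiber drive: pons cells emit
#'   8 Hz Poisson spikes; per-population mean rates are measured after the
#'   warmup.
#' * `run_strong_input()` — sustained strong mossy-fiber drive (50 Hz pons),
#'   the condition under which granule cells express random burst/silent
#'   alternation; returns the spikes needed for raster and similarity-index
#'   analysis.
#' * `run_okr()` — the optokinetic-response protocol: the OKR model variant
#'   with NRTP and vestibular-nucleus (VN) sheets, a non-negative sinusoidal
#'   current into NRTP (minimum at t = 0), cosine fits of the NRTP, Purkinje
#'   and VN rate traces at the stimulus frequency.
#'
#' Experiments default to a periodic boundary so a single simulated tile
#' behaves like an interior tile of a large array.
#'
#' @param density Density factor passed to [scale_tile_spec()].
#' @param duration Total simulated time (ms), warmup included.
#' @param warmup Initial span (ms) excluded from all rate measurements.
#' @param seed Master seed.
#' @param tile_grid Tile layout.
#' @param boundary `"periodic"` (default) or `"open"`.
#' @param record Populations to record (default: all).
#' @return A `cb_experiment` object: `spikes`, per-population `rates`,
#'   `timing`, the measurement `window`, `n_cells`, and for the OKR the rate
#'   `traces` and cosine `fits`.
#' @examples
#' ex <- run_resting_state(density = 0.01, duration = 700, warmup = 200)
#' ex$rates
#' @name experiments
NULL

.run_experiment <- function(spec, settings, condition, warmup,
                            record = NULL, rate_pops = NULL) {
  net <- build_network(spec, settings)
  sim <- run_simulation(net, record = record)
  window <- c(warmup, settings$duration)
  rate_pops <- rate_pops %||% record %||% .cb_pop_order(spec)
  rates <- tibble(
    population = rate_pops,
    rate_hz = vapply(rate_pops, function(p)
      mean_firing_rate(sim, p, window), numeric(1))
  )
  structure(
    list(spikes = sim$spikes, rates = rates, timing = sim$timing,
         window = window, n_cells = sim$n_cells, duration = settings$duration,
         dt = settings$dt, seed = settings$seed, condition = condition,
         spec = spec, settings = settings,
         n_synapses = sum(net$summary$n_synapses)),
    class = c("cb_experiment", "cb_sim")
  )
}

#' @rdname experiments
#' @export
run_resting_state <- function(density = 1, duration = 2500, warmup = 500,
                              seed = 1, tile_grid = c(1L, 1L),
                              boundary = "periodic", record = NULL) {
  spec <- scale_tile_spec(cerebellar_tile_spec(), density)
  settings <- simulation_settings(duration = duration, seed = seed,
                                  tile_grid = tile_grid, warmup = warmup,
                                  boundary = boundary)
  .run_experiment(spec, settings, "resting", warmup, record = record)
}

#' @rdname experiments
#' @param rate_hz Pons drive rate for the strong-input condition (Hz).
#' @param pons_mode `"poisson"` (default): pons cells emit independent Poisson
#'   trains at `rate_hz`; `"pacemaker"`: the Poisson driver is removed and
#'   pons cells pace intrinsically from their constant drive (about 53 Hz).
#' @export
run_strong_input <- function(density = 1, duration = 2500, warmup = 500,
                             seed = 1, tile_grid = c(1L, 1L),
                             boundary = "periodic", record = NULL,
                             rate_hz = 50, pons_mode = c("poisson", "pacemaker")) {
  pons_mode <- match.arg(pons_mode)
  spec <- scale_tile_spec(cerebellar_tile_spec(), density)
  if (pons_mode == "poisson") {
    spec$drivers$rate_hz[spec$drivers$population == "Pons"] <- rate_hz
  } else {
    spec$drivers <- spec$drivers[spec$drivers$population != "Pons", ]
  }
  settings <- simulation_settings(duration = duration, seed = seed,
                                  tile_grid = tile_grid, warmup = warmup,
                                  boundary = boundary)
  .run_experiment(spec, settings, "strong_input", warmup, record = record)
}

#' @rdname experiments
#' @param cycles Number of stimulus cycles simulated after the warmup.
#' @param period_ms Stimulus period (ms).
#' @param amplitude Peak sinusoidal drive into NRTP.
#' @param bin_ms Rate-trace bin width (ms) for the cosine fits.
#' @export
run_okr <- function(density = 1, cycles = 2, period_ms = 2000, amplitude = 18,
                    warmup = 500, seed = 1, tile_grid = c(1L, 1L),
                    boundary = "periodic", record = NULL, bin_ms = 50) {
  if (cycles < 1) abort("cycles must be >= 1")
  spec <- scale_tile_spec(okr_tile_spec(period_ms, amplitude), density)
  duration <- warmup + cycles * period_ms
  settings <- simulation_settings(duration = duration, seed = seed,
                                  tile_grid = tile_grid, warmup = warmup,
                                  boundary = boundary)
  ex <- .run_experiment(spec, settings, "okr", warmup, record = record)

  window <- c(warmup, duration)
  freq_hz <- 1000 / period_ms
  fit_pops <- intersect(c("NRTP", "PC", "VN"), unique(ex$spikes$population))
  ex$traces <- bind_rows(lapply(fit_pops, function(p)
    rate_trace(ex, p, window, bin_ms = bin_ms)))
  ex$fits <- stats::setNames(lapply(fit_pops, function(p)
    cosine_fit(ex$traces[ex$traces$population == p, ], freq_hz)), fit_pops)
  ex$period_ms <- period_ms
  ex
}

#' Desk-scale weak-scaling benchmark
#'
#' Runs the same per-tile model over increasing tile counts and reports the
#' per-bucket computational time. With a constant per-tile load, good weak
#' scaling means the per-tile neuron and synapse seconds stay flat as tiles
#' are added. Execution is sequential (one process), so wall-clock totals grow
#' with the tile count; the per-tile buckets are the quantity of interest.
#'
#' @param tile_counts Tile counts to benchmark; perfect squares give square
#'   arrays, other values a 1-row strip.
#' @param density Density factor for the per-tile model.
#' @param duration Simulated time (ms) per row.
#' @param seed Master seed.
#' @return A tibble: `tiles`, `neurons`, `synapses`, `neuron_s`, `synapse_s`,
#'   `communication_s`, `total_s` (summed across tiles), and the per-tile
#'   means `neuron_s_per_tile`, `synapse_s_per_tile`. Rows that fail (e.g.,
#'   memory exhaustion) are kept with `NA` times.
#' @export
run_scaling_benchmark <- function(tile_counts = c(1, 4), density = 0.01,
                                  duration = 500, seed = 1) {
  spec <- scale_tile_spec(cerebellar_tile_spec(), density)
  rows <- lapply(tile_counts, function(nt) {
    k <- sqrt(nt)
    grid <- if (abs(k - round(k)) < 1e-9) c(as.integer(k), as.integer(k))
            else c(as.integer(nt), 1L)
    tryCatch({
      settings <- simulation_settings(duration = duration, seed = seed,
                                      tile_grid = grid, boundary = "periodic")
      net <- build_network(spec, settings)
      sim <- run_simulation(net, record = character(0))
      tm <- sim$timing
      tibble(tiles = nt,
             neurons = sum(net$geometry$n_total),
             synapses = sum(net$summary$n_synapses),
             neuron_s = sum(tm$neuron_s), synapse_s = sum(tm$synapse_s),
             communication_s = sum(tm$communication_s),
             total_s = sum(tm$total_s),
             neuron_s_per_tile = mean(tm$neuron_s),
             synapse_s_per_tile = mean(tm$synapse_s))
    }, error = function(e) {
      tibble(tiles = nt, neurons = NA_real_, synapses = NA_real_,
             neuron_s = NA_real_, synapse_s = NA_real_,
             communication_s = NA_real_, total_s = NA_real_,
             neuron_s_per_tile = NA_real_, synapse_s_per_tile = NA_real_)
    })
  })
  bind_rows(rows)
}

#' @export
print.cb_experiment <- function(x, ...) {
  cat(sprintf("<cb_experiment: %s> %g ms (warmup %g), seed %d\n",
              x$condition, x$duration, x$window[1], x$seed))
  print(x$rates)
  invisible(x)
}
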