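#' Population-mean firing rate
#'
#' Total spikes of a population inside the window divided by cell count and
#' window length; silent cells stay in the denominator.
#'
#' @param sim A `cb_sim`/`cb_experiment` result, or a spike tibble (then
#'   `n_cells` is mandatory).
#' @param population Population name.
#' @param window `c(t0, t1)` in ms, half-open `[t0, t1)`.
#' @param n_cells Number of cells in the population (only for raw tibbles).
#' @return Mean rate in Hz.
#' @examples
#' spk <- tibble::tibble(t_ms = c(10, 20), gid = c(0, 0), population = "PC")
#' mean_firing_rate(spk, "PC", c(0, 1000), n_cells = 2)  # 1 Hz
#' @export
mean_firing_rate <- function(sim, population, window, n_cells = NULL) {
  spikes <- if (inherits(sim, c("cb_sim", "cb_experiment"))) sim$spikes else sim
  if (is.null(n_cells)) {
    if (!inherits(sim, c("cb_sim", "cb_experiment"))) {
      abort("n_cells is required when passing a raw spike table")
    }
    n_cells <- sim$n_cells[[population]]
    if (is.null(n_cells) || is.na(n_cells)) {
      abort(sprintf("unknown population '%s'", population))
    }
  }
  if (window[2] <= window[1]) abort("empty window: t1 must exceed t0")
  k <- sum(spikes$population == population &
             spikes$t_ms >= window[1] & spikes$t_ms < window[2])
  k / (n_cells * (window[2] - window[1]) / 1000)
}

#' Binned population rate trace
#'
#' @inheritParams mean_firing_rate
#' @param bin_ms Bin width (ms); must divide the window length.
#' @return A `cb_ratetrace` tibble: `population`, `t_mid` (bin center, ms),
#'   `rate_hz` (population-mean rate in the bin).
#' @export
rate_trace <- function(sim, population, window, bin_ms = 50, n_cells = NULL) {
  spikes <- if (inherits(sim, c("cb_sim", "cb_experiment"))) sim$spikes else sim
  if (is.null(n_cells)) n_cells <- sim$n_cells[[population]]
  nbin <- (window[2] - window[1]) / bin_ms
  if (abs(nbin - round(nbin)) > 1e-9) {
    abort("bin_ms must divide the window length")
  }
  nbin <- as.integer(round(nbin))
  tt <- spikes$t_ms[spikes$population == population &
                      spikes$t_ms >= window[1] & spikes$t_ms < window[2]]
  idx <- pmin(nbin - 1L, as.integer((tt - window[1]) %/% bin_ms))
  counts <- tabulate(idx + 1L, nbins = nbin)
  out <- tibble(
    population = population,
    t_mid = window[1] + (seq_len(nbin) - 0.5) * bin_ms,
    rate_hz = counts / (n_cells * bin_ms / 1000)
  )
  class(out) <- c("cb_ratetrace", class(out))
  out
}

#' Exponentially filtered spike traces
#'
#' For each selected neuron, the running exponential filter of its spike train
#' (the shape of the depolarization it would contribute downstream):
#' `z_i(t) = (1/tau) * sum over spikes s <= t of exp(-(t - s)/tau)`,
#' computed by the per-step recurrence
#' `z <- z * exp(-dt/tau) + f_i(t)/tau` on the integration grid.
#'
#' @param sim Result object or spike tibble.
#' @param gids Neuron ids to trace.
#' @param window `c(t0, t1)` ms; the grid runs from `t0` to `t1` in steps of
#'   `dt`. Spikes before `t0` are ignored (traces start from zero).
#' @param tau_pc Filter time constant (ms), default 50.
#' @param dt Grid step (ms), default the run's `dt`.
#' @return A `cb_ztrace` object: `z` is a `length(t_grid) x length(gids)`
#'   matrix, plus `t_grid`, `gids`, `tau_pc`, `dt`.
#' @export
compute_z_traces <- function(sim, gids, window, tau_pc = 50, dt = NULL) {
  spikes <- if (inherits(sim, c("cb_sim", "cb_experiment"))) sim$spikes else sim
  if (is.null(dt)) {
    dt <- if (!is.data.frame(sim) && is.list(sim) && !is.null(sim[["dt"]]))
      sim[["dt"]] else 0.1
  }
  if (tau_pc <= 0) abort("tau_pc must be > 0")
  t_grid <- seq(window[1], window[2], by = dt)
  nt <- length(t_grid)
  nn <- length(gids)
  decay <- exp(-dt / tau_pc)

  spikes <- spikes[spikes$gid %in% gids &
                     spikes$t_ms >= window[1] & spikes$t_ms <= window[2], ]
  col <- match(spikes$gid, gids)
  row <- as.integer(round((spikes$t_ms - window[1]) / dt)) + 1L

  z <- matrix(0, nt, nn)
  imp <- matrix(0, nt, nn)
  imp[cbind(row, col)] <- 1 / tau_pc
  for (j in seq_len(nn)) {
    z[, j] <- stats::filter(imp[, j], decay, method = "recursive")
  }
  structure(list(z = z, t_grid = t_grid, gids = gids, tau_pc = tau_pc,
                 dt = dt),
            class = "cb_ztrace")
}

#' Similarity index of population activity
#'
#' The time-averaged cosine similarity between the population vectors of
#' filtered activity separated by a lag:
#' `SI(dt) = (1/T) * sum over t of <z(t), z(t + dt)> / (||z(t)|| ||z(t + dt)||)`,
#' averaged over `t` in `[t0, t0 + T]` on the trace grid. `SI(0) = 1` by
#' construction and `SI` stays in `[0, 1]` because the traces are
#' non-negative. Grid points where either norm vanishes (e.g., before the
#' first spike) are excluded from the average; their count is reported.
#'
#' @param ztrace A `cb_ztrace` from [compute_z_traces()].
#' @param delta_ms Lag grid (ms); defaults to 0-500 ms in 10 ms steps.
#' @param T_ms Averaging duration (ms), default 2000. `t0` is the start of the
#'   trace window; `t0 + T_ms + max(delta_ms)` must not exceed its end.
#' @return A `cb_sicurve` tibble: `delta_ms`, `si`, `n_excluded`.
#' @export
similarity_index <- function(ztrace, delta_ms = seq(0, 500, by = 10),
                             T_ms = 2000) {
  z <- ztrace$z
  dt <- ztrace$dt
  nt <- nrow(z)
  n_base <- as.integer(round(T_ms / dt)) + 1L
  lag_steps <- as.integer(round(delta_ms / dt))
  if (n_base + max(lag_steps) > nt) {
    abort("trace too short for the requested T and lag grid")
  }
  norms <- sqrt(rowSums(z * z))
  base <- seq_len(n_base)
  si <- numeric(length(lag_steps))
  nex <- integer(length(lag_steps))
  for (i in seq_along(lag_steps)) {
    sh <- base + lag_steps[i]
    num <- rowSums(z[base, , drop = FALSE] * z[sh, , drop = FALSE])
    den <- norms[base] * norms[sh]
    ok <- den > 0
    if (!any(ok)) abort("similarity undefined: all time bins degenerate")
    si[i] <- mean(num[ok] / den[ok])
    nex[i] <- sum(!ok)
  }
  out <- tibble(delta_ms = delta_ms, si = si, n_excluded = nex)
  class(out) <- c("cb_sicurve", class(out))
  out
}

#' Cosine fit of a modulated rate trace
#'
#' Least-squares fit of `rate(t) = a + b * cos(2 pi f t + phi)` by linear
#' regression on the cosine and sine components at the stimulus frequency.
#' The amplitude is reported non-negative (the phase absorbs the sign).
#'
#' @param trace A rate-trace tibble with `t_mid` (ms) and `rate_hz`.
#' @param freq_hz Stimulus frequency (Hz).
#' @return A `cb_cosfit` object with fields `a` (offset, Hz), `b` (amplitude,
#'   Hz), `phi` (rad), `freq_hz`, `r_squared`, `n_bins`.
#' @examples
#' tr <- tibble::tibble(t_mid = seq(25, 1975, 50),
#'                      rate_hz = 35 + 15 * cos(2 * pi * seq(25, 1975, 50) / 2000))
#' cosine_fit(tr, 0.5)
#' @export
cosine_fit <- function(trace, freq_hz) {
  if (nrow(trace) < 3) abort("cosine fit needs at least 3 bins")
  if (freq_hz <= 0) abort("freq_hz must be > 0")
  if (diff(range(trace$t_mid)) < 1000 / freq_hz - 1e-9 &&
      nrow(trace) * (trace$t_mid[2] - trace$t_mid[1]) < 1000 / freq_hz - 1e-9) {
    abort("trace must span at least one stimulus cycle")
  }
  w <- 2 * pi * freq_hz * trace$t_mid / 1000
  fit <- lm(rate_hz ~ cos(w) + sin(w), data = trace)
  cf <- coef(fit)
  bc <- cf[[2]]
  bs <- cf[[3]]
  structure(
    list(a = cf[[1]], b = sqrt(bc^2 + bs^2), phi = atan2(-bs, bc),
         freq_hz = freq_hz, r_squared = summary(fit)$r.squared,
         n_bins = nrow(trace)),
    class = "cb_cosfit"
  )
}

#' @export
print.cb_cosfit <- function(x, ...) {
  cat(sprintf(
    "<cb_cosfit> rate ~ %.2f + %.2f cos(2pi %g t + %.2f), R^2 = %.3f\n",
    x$a, x$b, x$freq_hz, x$phi, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cosine_fit
#' @param x A `cb_cosfit`.
#' @param ... Unused.
#' @export
tidy.cb_cosfit <- function(x, ...) {
  tibble(term = c("offset", "amplitude", "phase"),
         estimate = c(x$a, x$b, x$phi),
         unit = c("Hz", "Hz", "rad"))
}

#' @rdname cosine_fit
#' @export
glance.cb_cosfit <- function(x, ...) {
  rng <- modulation_range(x)
  tibble(offset_hz = x$a, amplitude_hz = x$b, phase_rad = x$phi,
         freq_hz = x$freq_hz, r_squared = x$r_squared, n_bins = x$n_bins,
         rate_min_hz = rng[1], rate_max_hz = rng[2])
}

#' Modulation range of a cosine fit
#'
#' The fitted rate swings over `[a - b, a + b]`, floored at zero.
#'
#' @param fit A `cb_cosfit`.
#' @return `c(min_hz, max_hz)`.
#' @export
modulation_range <- function(fit) {
  c(max(0, fit$a - fit$b), max(0, fit$a + fit$b))
}

#' Raster rows for a sample of neurons
#'
#' Draws a reproducible sample of neurons from one population and returns
#' their spikes as (time, row index) pairs for raster plotting.
#'
#' @param sim Result object.
#' @param population Population to sample.
#' @param n_neurons Sample size.
#' @param window `c(t0, t1)` ms.
#' @param sample_seed Seed for the sample draw.
#' @return A tibble `t_ms`, `row` (0-based row index), `gid`.
#' @export
spike_raster_table <- function(sim, population, n_neurons = 1024,
                               window = NULL, sample_seed = 1) {
  spikes <- sim$spikes
  geo <- .pop_geometry(sim$spec, sim$settings)
  gg <- geo[geo$population == population, ]
  window <- window %||% c(0, sim$duration)
  pool <- gg$gid_base + seq_len(gg$n_total) - 1L
  n_neurons <- min(n_neurons, length(pool))
  # deterministic keyed permutation (no global RNG state touched)
  key <- (as.numeric(pool + 1) * 2654435761 + sample_seed * 40503) %% 2^32
  chosen <- sort(pool[order(key, pool)[seq_len(n_neurons)]])
  sel <- spikes[spikes$population == population &
                  spikes$gid %in% chosen &
                  spikes$t_ms >= window[1] & spikes$t_ms < window[2], ]
  out <- tibble(t_ms = sel$t_ms,
                row = match(sel$gid, chosen) - 1L,
                gid = sel$gid)
  class(out) <- c("cb_raster", class(out))
  out
}
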