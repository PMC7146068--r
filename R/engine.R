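#' Closed-form alpha-function conductance
#'
#' `weight * (t / tau) * exp(1 - t / tau)`: the conductance waveform a single
#' presynaptic spike at `t = 0` evokes, peak-normalized so it reaches `weight`
#' at `t = tau`. The engine's two-stage filter recurrence reproduces this form
#' exactly at the integration grid times.
#'
#' @param t_since_spike Time since the spike (ms), non-negative.
#' @param tau_syn Alpha time constant (ms).
#' @param weight Peak conductance.
#' @return Conductance value(s).
#' @examples
#' alpha_conductance(2, tau_syn = 2)    # peak = 1
#' alpha_conductance(4, tau_syn = 2)    # 2 * exp(-1)
#' @export
alpha_conductance <- function(t_since_spike, tau_syn, weight = 1) {
  if (any(t_since_spike < 0)) abort("t_since_spike must be >= 0")
  weight * (t_since_spike / tau_syn) * exp(1 - t_since_spike / tau_syn)
}

#' Engine recurrence trace of the alpha filter
#'
#' Runs the exact-exponential two-stage recurrence the engine uses for
#' synaptic conductances on an isolated filter hit by a single spike at
#' `t = 0`, returning g on the grid `0, dt, ..., n_steps * dt`. Useful to
#' check the recurrence against [alpha_conductance()].
#'
#' @param n_steps Number of steps to advance.
#' @param dt Step (ms).
#' @param tau_syn Alpha time constant (ms).
#' @param weight Peak conductance.
#' @return Numeric vector of length `n_steps + 1`.
#' @examples
#' max(alpha_filter_trace(200, 0.1, 2)) # ~1 at t = tau
#' @export
alpha_filter_trace <- function(n_steps, dt, tau_syn, weight = 1) {
  if (dt <= 0 || tau_syn <= 0) abort("dt and tau_syn must be > 0")
  cpp_alpha_filter_trace(as.integer(n_steps), 0L, dt, tau_syn, weight)
}

#' Closed-form inter-spike interval of an isolated pacemaking LIF neuron
#'
#' With constant suprathreshold drive and no synaptic input the
#' leaky integrate-and-fire interval is
#' `t_ref + tau_m * log((e_rest + i_ex - v_reset) / (e_rest + i_ex - theta))`,
#' which reduces to `t_ref + tau_m * log(i_ex / (i_ex - (theta - e_rest)))`
#' when `v_reset == e_rest`. Returns `Inf` below rheobase.
#'
#' @param tau_m,theta,v_reset,e_rest,i_ex,t_ref Neuron parameters (ms, mV).
#' @return Interval in ms.
#' @examples
#' lif_isi(10, -50, -70, -70, 22, 1)   # Purkinje-like pacing, ~25 ms
#' @export
lif_isi <- function(tau_m, theta, v_reset, e_rest, i_ex, t_ref = 0) {
  v_inf <- e_rest + i_ex
  ifelse(v_inf <= theta, Inf,
         t_ref + tau_m * log((v_inf - v_reset) / (v_inf - theta)))
}

# receptor channels: one filter bank per (post population, tau_syn, e_rev)
.derive_channels <- function(spec) {
  rc <- left_join(spec$receptors,
                  spec$projections[, c("projection", "post")],
                  by = "projection")
  pops <- .cb_pop_order(spec)
  rc$pop_idx <- match(rc$post, pops)
  ch <- dplyr::distinct(rc[, c("pop_idx", "post", "tau_syn", "e_rev")])
  ch <- arrange(ch, .data$pop_idx, .data$tau_syn, .data$e_rev)
  ch$chan <- seq_len(nrow(ch)) - 1L
  rc <- left_join(rc, ch, by = c("pop_idx", "post", "tau_syn", "e_rev"))
  list(channels = ch, receptor_chan = rc$chan)
}

#' Run a built network
#'
#' Advances the model by forward Euler at the settings' fixed time step.
#' Within every step, spikes emitted at the end of the previous step are
#' delivered to their target receptor filters (one-step synaptic delay for all
#' projections, including cross-tile ones), the alpha filters advance by their
#' exact exponential-integrator recurrence, and each non-refractory membrane
#' takes one Euler step of
#' `tau_m dv/dt = -(v - e_rest) - sum_r g_r (v - e_rev_r) + i_ex + drive(t)`.
#' Threshold crossings reset to `v_reset`, clamp there for the absolute
#' refractory period and are recorded at the step's end time. Membrane
#' potentials start at rest, filters at zero. Populations under a
#' `poisson_rate` driver emit memorylessly (probability `rate * dt` per step,
#' replacing the membrane dynamics entirely, refractoriness included).
#'
#' The run is reproducible: spike output depends only on (spec, settings
#' seed, tile layout), never on the scheduler or the nominal worker count.
#'
#' @param net A `cb_network` from [build_network()].
#' @param duration Override of the settings' duration (ms).
#' @param record Character vector of populations whose spikes to keep
#'   (default: all). Unrecorded populations still participate fully.
#' @param scheduler `"tiled"` (per-tile stepping with per-tile timing and halo
#'   bookkeeping) or `"global"` (whole populations at once); both give
#'   bit-identical spike output.
#' @return A `cb_sim` object: `spikes` (tibble `t_ms`, `gid`, `population`),
#'   `timing` (per-tile neuron/synapse/communication/total seconds), plus the
#'   run metadata.
#' @examples
#' net <- build_network(scale_tile_spec(cerebellar_tile_spec(), 0.01),
#'                      simulation_settings(200, seed = 7))
#' sim <- run_simulation(net)
#' head(sim$spikes)
#' @export
run_simulation <- function(net, duration = NULL, record = NULL,
                           scheduler = c("tiled", "global")) {
  stopifnot(inherits(net, "cb_network"))
  scheduler <- match.arg(scheduler)
  spec <- net$spec
  settings <- net$settings
  duration <- duration %||% settings$duration
  n_steps <- as.integer(round(duration / settings$dt))
  geo <- net$geometry
  pops <- .cb_pop_order(spec)
  record <- record %||% pops
  if (!all(record %in% pops)) {
    abort(sprintf("unknown population(s): %s",
                  paste(setdiff(record, pops), collapse = ", ")))
  }

  dr <- spec$drivers
  pops_in <- lapply(seq_along(pops), function(i) {
    p <- pops[i]
    nr <- spec$neurons[spec$neurons$population == p, ]
    gg <- geo[geo$population == p, ]
    d_pois <- dr[dr$population == p & dr$mode == "poisson_rate", ]
    d_sin <- dr[dr$population == p & dr$mode == "sinusoid_current", ]
    d_const <- dr[dr$population == p & dr$mode == "constant_current", ]
    list(
      n = as.integer(gg$n_total), per_tile = as.integer(gg$per_tile),
      gid_base = as.integer(gg$gid_base),
      tau_m = nr$tau_m, theta = nr$theta, v_reset = nr$v_reset,
      e_rest = nr$e_rest, i_ex = nr$i_ex,
      t_ref_steps = as.integer(round(nr$t_ref / settings$dt)),
      mode = if (nrow(d_pois) > 0) 1L else 0L,
      rate_hz = if (nrow(d_pois) > 0) d_pois$rate_hz[1] else 0,
      sin_amp = if (nrow(d_sin) > 0) d_sin$amplitude[1] else 0,
      sin_period = if (nrow(d_sin) > 0) d_sin$period_ms[1] else 0,
      sin_phase = if (nrow(d_sin) > 0) d_sin$phase[1] else 0,
      const_cur = if (nrow(d_const) > 0) d_const$amplitude[1] else 0,
      record = p %in% record
    )
  })

  chd <- .derive_channels(spec)
  chans_in <- lapply(seq_len(nrow(chd$channels)), function(i) {
    list(pop = chd$channels$pop_idx[i] - 1L,
         tau_syn = chd$channels$tau_syn[i],
         e_rev = chd$channels$e_rev[i])
  })

  projs_in <- lapply(seq_len(nrow(spec$projections)), function(i) {
    pr <- spec$projections[i, ]
    rows <- which(spec$receptors$projection == pr$projection)
    list(
      pre_pop = match(pr$pre, pops) - 1L,
      offsets = net$edges[[i]]$offsets,
      targets = net$edges[[i]]$targets,
      receptors = lapply(rows, function(r) {
        list(chan = chd$receptor_chan[r],
             impulse = spec$receptors$weight[r] * exp(1))
      })
    )
  })

  n_tiles <- prod(settings$tile_grid)
  halo_flag <- integer(0)
  if (n_tiles > 1 && !is.null(net$halo) && nrow(net$halo) > 0) {
    halo_flag <- integer(sum(geo$n_total))
    halo_flag[unique(net$halo$gid) + 1L] <- 1L
  }

  seed64 <- .split_seed(settings$seed)
  res <- cpp_run_simulation(pops_in, chans_in, projs_in, n_steps,
                            settings$dt, seed64[1], seed64[2],
                            as.integer(n_tiles),
                            if (scheduler == "tiled") 1L else 0L, halo_flag)

  pop_of <- findInterval(res$gid, geo$gid_base)
  spikes <- tibble(
    t_ms = res$step * settings$dt,
    gid = res$gid,
    population = pops[pop_of]
  )
  timing <- tibble(
    tile = seq_len(n_tiles) - 1L,
    neuron_s = res$timing[, 1], synapse_s = res$timing[, 2],
    communication_s = res$timing[, 3], total_s = res$timing[, 4]
  )
  counts <- .pop_counts(spec)
  ntile_counts <- counts * n_tiles

  structure(
    list(spikes = spikes, timing = timing, duration = duration,
         dt = settings$dt, seed = settings$seed,
         n_cells = stats::setNames(as.numeric(ntile_counts),
                                   names(ntile_counts)),
         settings = settings, spec = spec, scheduler = scheduler),
    class = "cb_sim"
  )
}

#' @export
print.cb_sim <- function(x, ...) {
  cat(sprintf("<cb_sim> %g ms, %s spikes, seed %d\n",
              x$duration, format(nrow(x$spikes), big.mark = ","), x$seed))
  invisible(x)
}

#' Write a spike record to TSV
#'
#' One row per event, sorted by (time, gid):
#' `t_ms`, `gid`, `population`, `x_um`, `y_um`, `z_um`.
#'
#' @param sim A `cb_sim` (or `cb_experiment`) result.
#' @param path Output file.
#' @param placements Placement table used to attach positions; defaults to
#'   re-deriving it from the run's spec and settings.
#' @return `path`, invisibly.
#' @export
write_spikes_tsv <- function(sim, path, placements = NULL) {
  placements <- placements %||% place_populations(sim$spec, sim$settings)
  rows <- left_join(sim$spikes, placements[, c("gid", "x", "y", "z")],
                    by = "gid")
  rows <- rows[, c("t_ms", "gid", "population", "x", "y", "z")]
  names(rows) <- c("t_ms", "gid", "population", "x_um", "y_um", "z_um")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike TSV written by [write_spikes_tsv()]
#' @param path File path.
#' @return A tibble with at least `t_ms`, `gid`, `population`.
#' @export
read_spikes_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
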