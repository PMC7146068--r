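#' Declarative tile model specification
#'
#' A `cb_spec` describes one tile of a layered-sheet spiking network as five
#' tibbles:
#'
#' * `layers` — one row per (layer, population) sheet stack: layer name,
#'   thickness (um), population, number of stacked sheets and per-sheet grid
#'   (`nx` by `ny` neurons).
#' * `neurons` — one row per population: membrane time constant `tau_m` (ms),
#'   threshold `theta` (mV), `v_reset` (mV), resting potential `e_rest` (mV),
#'   constant drive `i_ex` (steady depolarization in mV at unit leak), absolute
#'   refractory period `t_ref` (ms), and the transmitter the population
#'   releases (`"excitatory"`/`"inhibitory"`).
#' * `projections` — one row per projection: `kernel` is `"gaussian"`
#'   (peak probability `p`, spatial scale `sigma_um`, hard `cutoff_um`) or
#'   `"cross"` (axis-aligned rectangle: mediolateral half-extent
#'   `pre_width_um`, rostrocaudal full extent `post_width_um`, uniform
#'   probability `p`).
#' * `receptors` — one row per (projection, receptor): kind
#'   (`AMPA`/`NMDA`/`GABA_A`), alpha-function time constant `tau_syn` (ms),
#'   reversal potential `e_rev` (mV) and peak conductance `weight` per spike.
#' * `drivers` — external inputs: `poisson_rate` (replaces the cell's own
#'   dynamics with Poisson emission at `rate_hz`), `constant_current`, or
#'   `sinusoid_current` with `amplitude`, `period_ms`, `phase` delivering
#'   `amplitude * (1 - cos(2*pi*t/period + phase)) / 2`.
#'
#' @name cb_spec
NULL

.new_spec <- function(layers, neurons, projections, receptors, drivers) {
  structure(
    list(
      layers = layers, neurons = neurons, projections = projections,
      receptors = receptors, drivers = drivers
    ),
    class = "cb_spec"
  )
}

.proj_name <- function(pre, post) paste0(pre, "->", post)

#' Built-in cerebellar tile model
#'
#' The complete default model of one square millimeter of cerebellar cortex
#' plus afferents: seven stacked layers (upper/lower molecular, Purkinje,
#' granular, deep cerebellar nucleus, inferior olive, pons), per-tile neuron
#' counts (4,096 stellate, 1,024 each of basket/Purkinje/Golgi/DCN/pons cells,
#' 819,200 granule cells, one olivary cell), conductance-LIF parameters per
#' population, two-dimensional Gaussian kernels for Golgi-to-granule,
#' olive-to-Purkinje and pons-to-granule projections, orthogonal-cross
#' (parallel-fiber style) kernels for the molecular-layer and parallel-fiber
#' projections, alpha-synapse time constants and connection weights.
#'
#' The default driver models spontaneous mossy-fiber activity: pons cells emit
#' 8 Hz Poisson spike trains.
#'
#' @return A validated [cb_spec] object.
#' @examples
#' spec <- cerebellar_tile_spec()
#' sum(spec$layers$n_sheets * spec$layers$nx * spec$layers$ny)
#' @export
cerebellar_tile_spec <- function() {
  layers <- tibble(
    layer = c("molecular_upper", "molecular_lower", "pc_layer",
              "granular", "granular", "dcn", "io", "pons"),
    thickness_um = c(100, 100, 30, 200, 200, 100, 100, 200),
    population = c("ST", "BA", "PC", "GR", "GO", "DCN", "IO", "Pons"),
    n_sheets = c(4L, 1L, 1L, 8L, 1L, 1L, 1L, 1L),
    nx = c(32L, 32L, 32L, 320L, 32L, 32L, 1L, 32L),
    ny = c(32L, 32L, 32L, 320L, 32L, 32L, 1L, 32L)
  )

  neurons <- tibble(
    population = c("ST", "BA", "PC", "GR", "GO", "DCN", "IO", "Pons"),
    tau_m   = c(10, 10, 10, 7.2, 12, 10, 10, 10),
    theta   = c(-55, -55, -50, -35, -50, -40, -50, -50),
    v_reset = c(-70, -70, -70, -70, -70, -70, -70, -70),
    e_rest  = c(-70, -70, -70, -58, -70, -70, -70, -70),
    i_ex    = c(0, 0, 22, 0, 0, 32, 50, 24),
    t_ref   = c(1, 1, 1, 1, 1, 1, 1500, 1),
    transmitter = c("inhibitory", "inhibitory", "inhibitory", "excitatory",
                    "inhibitory", "excitatory", "excitatory", "excitatory")
  )

  g <- function(pre, post, p, sigma) {
    tibble(projection = .proj_name(pre, post), pre = pre, post = post,
           kernel = "gaussian", p = p, sigma_um = sigma, cutoff_um = 3 * sigma,
           pre_width_um = NA_real_, post_width_um = NA_real_)
  }
  x <- function(pre, post, pre_w, post_w, p) {
    tibble(projection = .proj_name(pre, post), pre = pre, post = post,
           kernel = "cross", p = p, sigma_um = NA_real_, cutoff_um = NA_real_,
           pre_width_um = pre_w, post_width_um = post_w)
  }
  projections <- bind_rows(
    g("GO", "GR", 0.04, 200),
    g("IO", "PC", 1, 350),
    g("Pons", "GR", 1, 25),
    x("ST", "ST", 50, 200, 0.02),
    x("ST", "PC", 50, 200, 0.1),
    x("BA", "BA", 50, 200, 0.02),
    x("BA", "PC", 50, 200, 0.1),
    x("PC", "BA", 50, 200, 0.05),
    x("PC", "DCN", 75, 600, 0.3),
    x("GR", "ST", 500, 100, 0.05),
    x("GR", "BA", 500, 100, 0.05),
    x("GR", "PC", 500, 100, 0.05),
    x("GR", "GO", 250, 100, 0.025)
  )

  r <- function(pre, post, kind, tau, weight) {
    e_rev <- if (kind %in% c("AMPA", "NMDA")) 0 else -80
    tibble(projection = .proj_name(pre, post), kind = kind,
           tau_syn = tau, e_rev = e_rev, weight = weight)
  }
  receptors <- bind_rows(
    r("GO", "GR", "GABA_A", 10, 3.0),
    r("IO", "PC", "AMPA", 2, 0.1),
    r("Pons", "GR", "AMPA", 2, 0.5),
    r("ST", "ST", "GABA_A", 2, 0.02),
    r("ST", "PC", "GABA_A", 2, 0.05),
    r("BA", "BA", "GABA_A", 2, 0.02),
    r("BA", "PC", "GABA_A", 2, 0.1),
    r("PC", "BA", "GABA_A", 2, 0.01),
    r("PC", "DCN", "GABA_A", 2, 0.0025),
    r("GR", "ST", "AMPA", 2, 0.00145),
    r("GR", "BA", "AMPA", 2, 0.00145),
    r("GR", "PC", "AMPA", 2, 0.0013),
    r("GR", "GO", "AMPA", 2, 0.0008),
    r("GR", "GO", "NMDA", 100, 0.00017)
  )

  drivers <- tibble(
    population = "Pons", mode = "poisson_rate",
    rate_hz = 8, amplitude = NA_real_, period_ms = NA_real_, phase = NA_real_
  )

  .new_spec(layers, neurons, projections, receptors, drivers)
}

# Peak conductance of the PC -> VN synapse. Calibrated once so that VN cells,
# inhibited by Purkinje cells firing at their steady baseline rate (57.4 Hz,
# delivered as Poisson trains through the PC->VN kernel), settle at a baseline
# of about 35 Hz; frozen thereafter (see the methods vignette).
.w_pc_vn <- 0.024

#' Built-in OKR extension of the cerebellar tile model
#'
#' Extends [cerebellar_tile_spec()] with the optokinetic-response circuitry:
#' a 32 x 32 NRTP sheet (membrane time constant 40 ms, threshold -60 mV, reset
#' and rest -70 mV, 1 ms refractory) relaying visual-motion drive into granule
#' cells through a Gaussian kernel (peak probability 0.1, sigma 75 um), and a
#' 32 x 32 vestibular-nucleus (VN) sheet receiving Purkinje-cell inhibition.
#' VN cells reuse the DCN membrane row with constant drive `i_ex = 40`; the
#' Purkinje drive is raised to `i_ex = 24`. NRTP cells receive a non-negative
#' sinusoidal current `A * (1 - cos(2*pi*t/period)) / 2` (default period 2 s,
#' `A = 18`, which makes the NRTP rate peak near 30 Hz); the 8 Hz pontine
#' background stays on.
#'
#' @param period_ms Stimulus period in ms.
#' @param amplitude Peak sinusoidal drive to NRTP (same units as `i_ex`).
#' @return A validated [cb_spec] object.
#' @export
okr_tile_spec <- function(period_ms = 2000, amplitude = 18) {
  spec <- cerebellar_tile_spec()

  spec$layers <- bind_rows(
    spec$layers,
    tibble(layer = c("dcn", "pons"), thickness_um = c(100, 200),
           population = c("VN", "NRTP"), n_sheets = c(1L, 1L),
           nx = c(32L, 32L), ny = c(32L, 32L))
  )

  dcn_row <- spec$neurons[spec$neurons$population == "DCN", ]
  spec$neurons <- bind_rows(
    spec$neurons,
    mutate(dcn_row, population = "VN", i_ex = 40),
    tibble(population = "NRTP", tau_m = 40, theta = -60, v_reset = -70,
           e_rest = -70, i_ex = 0, t_ref = 1, transmitter = "excitatory")
  )
  spec$neurons$i_ex[spec$neurons$population == "PC"] <- 24

  spec$projections <- bind_rows(
    spec$projections,
    tibble(projection = "NRTP->GR", pre = "NRTP", post = "GR",
           kernel = "gaussian", p = 0.1, sigma_um = 75, cutoff_um = 225,
           pre_width_um = NA_real_, post_width_um = NA_real_),
    # PC -> VN reuses the PC -> DCN projection geometry
    tibble(projection = "PC->VN", pre = "PC", post = "VN",
           kernel = "cross", p = 0.3, sigma_um = NA_real_, cutoff_um = NA_real_,
           pre_width_um = 75, post_width_um = 600)
  )
  spec$receptors <- bind_rows(
    spec$receptors,
    tibble(projection = "NRTP->GR", kind = "AMPA", tau_syn = 2, e_rev = 0,
           weight = 0.5),
    tibble(projection = "PC->VN", kind = "GABA_A", tau_syn = 2, e_rev = -80,
           weight = .w_pc_vn)
  )

  spec$drivers <- bind_rows(
    spec$drivers,
    tibble(population = "NRTP", mode = "sinusoid_current", rate_hz = NA_real_,
           amplitude = amplitude, period_ms = period_ms, phase = 0)
  )
  spec
}

#' Validate a tile model specification
#'
#' Checks every structural invariant of a [cb_spec] and returns the violations
#' as data (an empty tibble means the spec is valid): positive time constants
#' and thicknesses, probabilities in (0, 1], Gaussian cutoffs of at least three
#' sigma, `v_reset <= e_rest < theta`, non-negative weights and refractory
#' periods, excitatory reversal potentials above every threshold and inhibitory
#' ones at or below every resting potential, projections referring only to
#' declared populations, at least one receptor per projection, and driver rates
#' and periods in range.
#'
#' @param spec A [cb_spec].
#' @return A tibble with columns `path`, `constraint`, `value`.
#' @export
validate_spec <- function(spec) {
  v <- list()
  bad <- function(path, constraint, value) {
    v[[length(v) + 1L]] <<- tibble(path = path, constraint = constraint,
                                   value = as.character(value))
  }

  ly <- spec$layers
  for (i in seq_len(nrow(ly))) {
    if (!is.finite(ly$thickness_um[i]) || ly$thickness_um[i] <= 0) {
      bad(sprintf("layers[%s]", ly$layer[i]), "thickness_um > 0", ly$thickness_um[i])
    }
    if (ly$nx[i] < 1L || ly$ny[i] < 1L || ly$n_sheets[i] < 1L) {
      bad(sprintf("layers[%s:%s]", ly$layer[i], ly$population[i]),
          "grid and sheet counts >= 1",
          paste(ly$n_sheets[i], ly$nx[i], ly$ny[i]))
    }
    if (!ly$population[i] %in% spec$neurons$population) {
      bad(sprintf("layers[%s]", ly$layer[i]), "population declared in neurons",
          ly$population[i])
    }
  }

  nn <- spec$neurons
  for (i in seq_len(nrow(nn))) {
    p <- nn$population[i]
    if (!is.finite(nn$tau_m[i]) || nn$tau_m[i] <= 0) {
      bad(sprintf("neurons[%s].tau_m", p), "tau_m > 0", nn$tau_m[i])
    }
    if (!(nn$v_reset[i] <= nn$e_rest[i] && nn$e_rest[i] < nn$theta[i])) {
      bad(sprintf("neurons[%s]", p), "v_reset <= e_rest < theta",
          paste(nn$v_reset[i], nn$e_rest[i], nn$theta[i]))
    }
    if (nn$t_ref[i] < 0) bad(sprintf("neurons[%s].t_ref", p), "t_ref >= 0", nn$t_ref[i])
  }

  pr <- spec$projections
  for (i in seq_len(nrow(pr))) {
    nm <- pr$projection[i]
    for (side in c("pre", "post")) {
      pop <- pr[[side]][i]
      if (!pop %in% nn$population) {
        bad(sprintf("projections[%s].%s", nm, side),
            "population declared in neurons", pop)
      }
    }
    if (!is.finite(pr$p[i]) || pr$p[i] <= 0 || pr$p[i] > 1) {
      bad(sprintf("projections[%s].p", nm), "0 < p <= 1", pr$p[i])
    }
    if (pr$kernel[i] == "gaussian") {
      if (!is.finite(pr$sigma_um[i]) || pr$sigma_um[i] <= 0) {
        bad(sprintf("projections[%s].sigma_um", nm), "sigma > 0", pr$sigma_um[i])
      } else if (!is.finite(pr$cutoff_um[i]) ||
                 pr$cutoff_um[i] < 3 * pr$sigma_um[i] - 1e-9) {
        bad(sprintf("projections[%s].cutoff_um", nm), "cutoff >= 3*sigma",
            pr$cutoff_um[i])
      }
    } else if (pr$kernel[i] == "cross") {
      if (!is.finite(pr$pre_width_um[i]) || pr$pre_width_um[i] <= 0 ||
          !is.finite(pr$post_width_um[i]) || pr$post_width_um[i] <= 0) {
        bad(sprintf("projections[%s]", nm), "cross widths > 0",
            paste(pr$pre_width_um[i], pr$post_width_um[i]))
      }
    } else {
      bad(sprintf("projections[%s].kernel", nm), "kernel in {gaussian, cross}",
          pr$kernel[i])
    }
    if (!nm %in% spec$receptors$projection) {
      bad(sprintf("projections[%s]", nm), "at least one receptor", "none")
    }
  }

  rc <- spec$receptors
  max_theta <- max(nn$theta)
  min_rest <- min(nn$e_rest)
  for (i in seq_len(nrow(rc))) {
    nm <- sprintf("receptors[%s:%s]", rc$projection[i], rc$kind[i])
    if (!rc$kind[i] %in% c("AMPA", "NMDA", "GABA_A")) {
      bad(nm, "kind in {AMPA, NMDA, GABA_A}", rc$kind[i])
    }
    if (!is.finite(rc$tau_syn[i]) || rc$tau_syn[i] <= 0) {
      bad(paste0(nm, ".tau_syn"), "tau_syn > 0", rc$tau_syn[i])
    }
    if (!is.finite(rc$weight[i]) || rc$weight[i] < 0) {
      bad(paste0(nm, ".weight"), "weight >= 0", rc$weight[i])
    }
    if (rc$kind[i] %in% c("AMPA", "NMDA") && rc$e_rev[i] <= max_theta) {
      bad(paste0(nm, ".e_rev"), "excitatory e_rev > all thresholds", rc$e_rev[i])
    }
    if (rc$kind[i] == "GABA_A" && rc$e_rev[i] > min_rest) {
      bad(paste0(nm, ".e_rev"), "inhibitory e_rev <= all resting potentials",
          rc$e_rev[i])
    }
    if (!rc$projection[i] %in% pr$projection) {
      bad(nm, "receptor attached to a declared projection", rc$projection[i])
    }
  }

  dr <- spec$drivers
  for (i in seq_len(nrow(dr))) {
    nm <- sprintf("drivers[%s]", dr$population[i])
    if (!dr$population[i] %in% nn$population) {
      bad(nm, "population declared in neurons", dr$population[i])
    }
    if (!dr$mode[i] %in% c("poisson_rate", "constant_current", "sinusoid_current")) {
      bad(nm, "mode known", dr$mode[i])
    }
    if (dr$mode[i] == "poisson_rate" &&
        (!is.finite(dr$rate_hz[i]) || dr$rate_hz[i] < 0)) {
      bad(paste0(nm, ".rate_hz"), "rate >= 0", dr$rate_hz[i])
    }
    if (dr$mode[i] == "sinusoid_current" &&
        (!is.finite(dr$period_ms[i]) || dr$period_ms[i] <= 0)) {
      bad(paste0(nm, ".period_ms"), "period > 0", dr$period_ms[i])
    }
  }

  if (length(v) == 0) {
    tibble(path = character(), constraint = character(), value = character())
  } else {
    bind_rows(v)
  }
}

.assert_valid_spec <- function(spec) {
  v <- validate_spec(spec)
  if (nrow(v) > 0) {
    abort(paste0(
      "validation error:\n",
      paste(sprintf("  %s: %s (got %s)", v$path, v$constraint, v$value),
            collapse = "\n")
    ))
  }
  invisible(spec)
}

#' Scale a tile model down (or keep it at full density)
#'
#' Produces a reduced-density variant of a spec for quick experiments: every
#' sheet's grid is scaled by `sqrt(density_factor)` per axis (rounded, floored
#' at one neuron), and the synaptic weights of every projection whose
#' presynaptic population shrank are multiplied by the actual count ratio
#' (old/new), so the expected summed synaptic drive per postsynaptic neuron is
#' preserved. Drivers are unchanged.
#'
#' @param spec A [cb_spec].
#' @param density_factor Fraction of the full neuron density, in (0, 1].
#' @return A [cb_spec].
#' @examples
#' s <- scale_tile_spec(cerebellar_tile_spec(), 0.25)
#' s$layers$nx[s$layers$population == "GR"]
#' @export
scale_tile_spec <- function(spec, density_factor) {
  if (!is.finite(density_factor) || density_factor <= 0 || density_factor > 1) {
    abort(sprintf("validation error: density_factor must be in (0, 1] (got %s)",
                  density_factor))
  }
  if (density_factor == 1) return(spec)
  ax <- sqrt(density_factor)

  old_counts <- .pop_counts(spec)
  spec$layers$nx <- pmax(1L, as.integer(round(spec$layers$nx * ax)))
  spec$layers$ny <- pmax(1L, as.integer(round(spec$layers$ny * ax)))
  new_counts <- .pop_counts(spec)

  ratio <- old_counts / new_counts
  for (i in seq_len(nrow(spec$receptors))) {
    proj <- spec$receptors$projection[i]
    pre <- spec$projections$pre[spec$projections$projection == proj]
    spec$receptors$weight[i] <- spec$receptors$weight[i] * ratio[[pre]]
  }
  spec
}

# per-tile neuron count by population (named numeric)
.pop_counts <- function(spec) {
  counts <- tapply(spec$layers$n_sheets * as.numeric(spec$layers$nx) * spec$layers$ny,
                   spec$layers$population, sum)
  counts[.cb_pop_order(spec)]
}

#' @export
print.cb_spec <- function(x, ...) {
  counts <- .pop_counts(x)
  cat(sprintf("<cb_spec> %d populations, %s neurons per tile, %d projections\n",
              length(counts), format(sum(counts), big.mark = ","),
              nrow(x$projections)))
  cat("  ", paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = " "), "\n")
  invisible(x)
}
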