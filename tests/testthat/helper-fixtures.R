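# shared fixtures: reduced-density models and independent oracles

# quick scaled model + settings
tiny_settings <- function(duration, seed = 1, ...) {
  simulation_settings(duration = duration, seed = seed, ...)
}

# single-population spec on a small grid, no projections (isolated neurons)
iso_spec <- function(pop, nx = 4L, ny = 4L) {
  sp <- cerebellar_tile_spec()
  sp$layers <- sp$layers[sp$layers$population == pop, ]
  sp$layers$nx <- nx
  sp$layers$ny <- ny
  sp$layers$n_sheets <- 1L
  sp$neurons <- sp$neurons[sp$neurons$population == pop, ]
  sp$projections <- sp$projections[0, ]
  sp$receptors <- sp$receptors[0, ]
  sp$drivers <- sp$drivers[0, ]
  sp
}

# exact expectation (and variance) of a projection's synapse count for given
# presynaptic cells, by direct summation of the kernel over the post lattice —
# the independent oracle for the stochastic wiring
lattice_expected_count <- function(spec, settings, projection, pre_idx = NULL) {
  pl <- place_populations(spec, settings)
  pr <- spec$projections[spec$projections$projection == projection, ]
  pre <- pl[pl$population == pr$pre, ]
  post <- pl[pl$population == pr$post, ]
  if (!is.null(pre_idx)) pre <- pre[pre_idx, ]
  Lx <- settings$tile_grid[1] * settings$tile_size
  Ly <- settings$tile_grid[2] * settings$tile_size
  mu <- 0
  varsum <- 0
  for (i in seq_len(nrow(pre))) {
    dx <- post$x - pre$x[i]
    dy <- post$y - pre$y[i]
    if (settings$boundary == "periodic") {
      dx <- dx - Lx * round(dx / Lx)
      dy <- dy - Ly * round(dy / Ly)
    }
    if (pr$kernel == "gaussian") {
      d2 <- dx^2 + dy^2
      p <- ifelse(d2 <= pr$cutoff_um^2,
                  pr$p * exp(-d2 / (2 * pr$sigma_um^2)), 0)
    } else {
      p <- ifelse(abs(dx) <= pr$pre_width_um &
                    abs(dy) <= pr$post_width_um / 2, pr$p, 0)
    }
    if (pr$pre == pr$post) p[post$gid == pre$gid[i]] <- 0  # no self-edge
    mu <- mu + sum(p)
    varsum <- varsum + sum(p * (1 - p))
  }
  list(mean = mu, sd = sqrt(varsum))
}

# brute-force filtered trace: direct evaluation of the exponential sum
# z_i(t) = (1/tau) * sum_{s <= t} exp(-(t - s)/tau) f_i(s)
brute_z_trace <- function(spike_t, t_grid, tau) {
  vapply(t_grid, function(t) {
    s <- spike_t[spike_t <= t + 1e-9]
    sum(exp(-(t - s) / tau)) / tau
  }, numeric(1))
}

# brute-force similarity index from a z matrix (time x neuron)
brute_si <- function(z, dt, delta_ms, T_ms) {
  n_base <- as.integer(round(T_ms / dt)) + 1L
  vapply(delta_ms, function(del) {
    lag <- as.integer(round(del / dt))
    num <- den <- numeric(n_base)
    for (i in seq_len(n_base)) {
      a <- z[i, ]
      b <- z[i + lag, ]
      num[i] <- sum(a * b)
      den[i] <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    }
    ok <- den > 0
    mean(num[ok] / den[ok])
  }, numeric(1))
}
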