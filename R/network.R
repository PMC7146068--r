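#' Place all populations on their sheet grids
#'
#' Neurons sit on evenly spaced per-sheet grids (spacing `tile_size / n`,
#' offset half a spacing from the tile edge), replicated across the tile
#' array. x runs mediolaterally (the parallel-fiber axis), y rostrocaudally,
#' and z is the depth of the sheet below the pial surface. Global ids are
#' contiguous per population, ordered (tile, sheet, row, column); placement is
#' a deterministic function of the spec and settings.
#'
#' @param spec A [cb_spec].
#' @param settings A [cb_settings].
#' @return A tibble with columns `population`, `gid`, `tile`, `x`, `y`, `z`.
#' @examples
#' pl <- place_populations(cerebellar_tile_spec(), simulation_settings(100))
#' nrow(pl[pl$population == "GR", ])
#' @export
place_populations <- function(spec, settings) {
  .assert_valid_spec(spec)
  geo <- .pop_geometry(spec, settings)
  out <- vector("list", nrow(geo))
  for (i in seq_len(nrow(geo))) {
    g <- geo[i, ]
    local <- 0:(g$n_total - 1)
    ix <- local %% g$nx
    iy <- (local %/% g$nx) %% g$ny
    s <- (local %/% (g$nx * g$ny)) %% g$n_sheets
    tl <- local %/% (g$nx * g$ny * g$n_sheets)
    tx <- tl %% settings$tile_grid[1]
    ty <- tl %/% settings$tile_grid[1]
    ts <- settings$tile_size
    out[[i]] <- tibble(
      population = g$population,
      gid = g$gid_base + local,
      tile = as.integer(tl),
      x = tx * ts + (ix + 0.5) * ts / g$nx,
      y = ty * ts + (iy + 0.5) * ts / g$ny,
      z = g$z_top + (s + 0.5) * g$thickness_um / g$n_sheets
    )
  }
  bind_rows(out)
}

# per-population geometry: grid shape, per-tile and total counts, gid bases,
# and the depth of the layer the population's sheets occupy
.pop_geometry <- function(spec, settings) {
  ly <- spec$layers
  if (anyDuplicated(ly$population)) {
    abort("validation error: each population must appear in exactly one layer row")
  }
  uniq_layers <- ly$layer[!duplicated(ly$layer)]
  th <- vapply(uniq_layers, function(l) max(ly$thickness_um[ly$layer == l]),
               numeric(1))
  z_top <- stats::setNames(cumsum(c(0, th[-length(th)])), uniq_layers)

  ntiles <- prod(settings$tile_grid)
  geo <- ly
  geo$per_tile <- geo$n_sheets * geo$nx * geo$ny
  geo$n_total <- geo$per_tile * ntiles
  geo$z_top <- z_top[geo$layer]
  geo <- geo[match(.cb_pop_order(spec), geo$population), ]
  geo$gid_base <- cumsum(c(0, geo$n_total[-nrow(geo)]))
  geo
}

#' Realize one projection of a spec
#'
#' Draws the synapses of a single projection with the kernel the spec assigns
#' to it: under the Gaussian kernel each (pre, post) pair at planar distance
#' `d <= cutoff` connects independently with probability
#' `p * exp(-d^2 / (2 sigma^2))`; under the orthogonal-cross kernel each post
#' cell inside the axis-aligned rectangle centered on the pre cell
#' (mediolateral extent `2 * pre_width`, rostrocaudal extent `post_width`)
#' connects with uniform probability `p`. z is ignored (kernels are planar);
#' self-edges are never drawn. One random sub-stream is opened per
#' (seed, projection, pre tile), so the wiring of a tile never depends on how
#' many other tiles exist.
#'
#' @param spec A [cb_spec].
#' @param settings A [cb_settings]; its `seed` and `boundary` govern the draw.
#' @param projection Projection name, e.g. `"GO->GR"`.
#' @return A tibble with columns `pre_gid`, `post_gid`.
#' @export
realize_projection <- function(spec, settings, projection) {
  geo <- .pop_geometry(spec, settings)
  pr <- spec$projections[spec$projections$projection == projection, ]
  if (nrow(pr) != 1) {
    abort(sprintf("validation error: unknown projection '%s'", projection))
  }
  pl <- place_populations(spec, settings)
  pre_pl <- pl[pl$population == pr$pre, ]
  raw <- .realize_raw(spec, settings, geo, pr, pre_pl,
                      proj_id = match(projection, spec$projections$projection))
  post_base <- geo$gid_base[geo$population == pr$post]
  n_per_pre <- diff(raw$offsets)
  tibble(
    pre_gid = rep(pre_pl$gid, n_per_pre),
    post_gid = post_base + raw$targets
  )
}

.realize_raw <- function(spec, settings, geo, pr, pre_pl, proj_id) {
  gpost <- geo[geo$population == pr$post, ]
  seed64 <- .split_seed(settings$seed)
  cpp_realize_projection(
    pre_x = pre_pl$x, pre_y = pre_pl$y, pre_tile = pre_pl$tile,
    kernel_type = if (pr$kernel == "gaussian") 0L else 1L,
    p = pr$p,
    sigma = pr$sigma_um %||% NA_real_,
    cutoff = if (pr$kernel == "gaussian") pr$cutoff_um else 0,
    pre_width = if (pr$kernel == "cross") pr$pre_width_um else 0,
    post_width = if (pr$kernel == "cross") pr$post_width_um else 0,
    ntx = settings$tile_grid[1], nty = settings$tile_grid[2],
    post_nx = gpost$nx, post_ny = gpost$ny, post_nsheets = gpost$n_sheets,
    tile_size = settings$tile_size,
    boundary = if (settings$boundary == "periodic") 1L else 0L,
    seed_lo = seed64[1], seed_hi = seed64[2],
    proj_id = proj_id, same_pop = pr$pre == pr$post
  )
}

# 32-bit halves of the master seed for the C++ side
.split_seed <- function(seed) c(seed %% 2^32, seed %/% 2^32)

#' Connect two populations with a 2-D Gaussian kernel
#'
#' Thin wrappers over [realize_projection()] for ad-hoc kernels that are not
#' part of the spec's projection list (used mainly to probe wiring
#' statistics).
#'
#' @inheritParams realize_projection
#' @param pre,post Population names.
#' @param p_peak,sigma,cutoff Gaussian kernel parameters (um).
#' @return A tibble with columns `pre_gid`, `post_gid`.
#' @export
connect_gaussian2d <- function(spec, settings, pre, post, p_peak, sigma,
                               cutoff = 3 * sigma) {
  spec$projections <- bind_rows(
    spec$projections,
    tibble(projection = "adhoc", pre = pre, post = post, kernel = "gaussian",
           p = p_peak, sigma_um = sigma, cutoff_um = cutoff,
           pre_width_um = NA_real_, post_width_um = NA_real_)
  )
  spec$receptors <- bind_rows(
    spec$receptors,
    tibble(projection = "adhoc", kind = "AMPA", tau_syn = 2, e_rev = 0, weight = 0)
  )
  realize_projection(spec, settings, "adhoc")
}

#' @rdname connect_gaussian2d
#' @param pre_width,post_width Cross kernel extents (um): mediolateral
#'   half-extent and rostrocaudal full extent.
#' @param p Uniform connection probability inside the rectangle.
#' @export
connect_orthogonal_cross <- function(spec, settings, pre, post, pre_width,
                                     post_width, p) {
  spec$projections <- bind_rows(
    spec$projections,
    tibble(projection = "adhoc", pre = pre, post = post, kernel = "cross",
           p = p, sigma_um = NA_real_, cutoff_um = NA_real_,
           pre_width_um = pre_width, post_width_um = post_width)
  )
  spec$receptors <- bind_rows(
    spec$receptors,
    tibble(projection = "adhoc", kind = "AMPA", tau_syn = 2, e_rev = 0, weight = 0)
  )
  realize_projection(spec, settings, "adhoc")
}

#' Analytic expected out-degree of a wiring kernel
#'
#' For an interior presynaptic neuron: the Gaussian kernel connects on average
#' `2 * pi * sigma^2 * p * rho * (1 - exp(-cutoff^2 / (2 sigma^2)))` posts
#' (cutoff-corrected mass) and the orthogonal-cross kernel
#' `2 * pre_width * post_width * p * rho`, where `rho` is the postsynaptic
#' areal density (cells per um^2).
#'
#' @param kernel `"gaussian"` or `"cross"`.
#' @param p Peak (Gaussian) or uniform (cross) connection probability.
#' @param post_density Postsynaptic density in cells per um^2.
#' @param sigma,cutoff Gaussian parameters (um).
#' @param pre_width,post_width Cross extents (um).
#' @return Expected synapse count per interior presynaptic neuron.
#' @examples
#' expected_degree("gaussian", p = 0.04, sigma = 200, cutoff = 600,
#'                 post_density = 819200 / 1000^2)
#' @export
expected_degree <- function(kernel, p, post_density, sigma = NULL,
                            cutoff = 3 * sigma, pre_width = NULL,
                            post_width = NULL) {
  if (kernel == "gaussian") {
    2 * pi * sigma^2 * p * post_density * (1 - exp(-cutoff^2 / (2 * sigma^2)))
  } else if (kernel == "cross") {
    2 * pre_width * post_width * p * post_density
  } else {
    abort(sprintf("unknown kernel '%s'", kernel))
  }
}

#' Build the full network graph
#'
#' Places every population and realizes every projection of the spec as
#' compressed adjacency, with one reproducible random sub-stream per
#' (projection, tile). For multi-tile layouts the halo map — which border
#' neurons each neighboring tile must hear about — is derived by scanning the
#' realized cross-tile edges.
#'
#' @param spec A [cb_spec].
#' @param settings A [cb_settings].
#' @return A `cb_network` object; its `summary` element tabulates realized
#'   synapse counts per projection.
#' @examples
#' net <- build_network(scale_tile_spec(cerebellar_tile_spec(), 0.01),
#'                      simulation_settings(100, seed = 1))
#' net$summary
#' @export
build_network <- function(spec, settings) {
  .assert_valid_spec(spec)
  .check_settings(settings)
  geo <- .pop_geometry(spec, settings)
  placements <- place_populations(spec, settings)

  edges <- vector("list", nrow(spec$projections))
  names(edges) <- spec$projections$projection
  counts <- numeric(nrow(spec$projections))
  for (i in seq_len(nrow(spec$projections))) {
    pr <- spec$projections[i, ]
    pre_pl <- placements[placements$population == pr$pre, ]
    edges[[i]] <- .realize_raw(spec, settings, geo, pr, pre_pl, proj_id = i)
    counts[i] <- length(edges[[i]]$targets)
  }

  net <- structure(
    list(
      spec = spec, settings = settings, geometry = geo,
      placements = placements, edges = edges,
      summary = tibble(projection = spec$projections$projection,
                       pre = spec$projections$pre,
                       post = spec$projections$post,
                       n_synapses = counts),
      halo = NULL
    ),
    class = "cb_network"
  )
  if (prod(settings$tile_grid) > 1) net$halo <- .halo_map(net)
  net
}

# halo map: for each ordered pair of distinct tiles, the presynaptic gids
# whose spikes the consuming tile needs (exactly the cross-tile edge sources)
.halo_map <- function(net) {
  geo <- net$geometry
  out <- list()
  for (i in seq_along(net$edges)) {
    pr <- net$spec$projections[i, ]
    e <- net$edges[[i]]
    gpre <- geo[geo$population == pr$pre, ]
    gpost <- geo[geo$population == pr$post, ]
    n_per_pre <- diff(e$offsets)
    pre_local <- rep.int(seq_len(gpre$n_total) - 1L, n_per_pre)
    pre_tile <- pre_local %/% gpre$per_tile
    post_tile <- e$targets %/% gpost$per_tile
    cross <- pre_tile != post_tile
    if (!any(cross)) next
    out[[length(out) + 1L]] <- dplyr::distinct(tibble(
      from_tile = pre_tile[cross],
      to_tile = post_tile[cross],
      gid = gpre$gid_base + pre_local[cross]
    ))
  }
  if (length(out) == 0) {
    return(tibble(from_tile = integer(), to_tile = integer(), gid = integer()))
  }
  arrange(dplyr::distinct(bind_rows(out)), .data$from_tile, .data$to_tile,
          .data$gid)
}

#' @export
print.cb_network <- function(x, ...) {
  cat(sprintf("<cb_network> %s neurons, %s synapses, %d x %d tiles (%s)\n",
              format(sum(x$geometry$n_total), big.mark = ","),
              format(sum(x$summary$n_synapses), big.mark = ","),
              x$settings$tile_grid[1], x$settings$tile_grid[2],
              x$settings$boundary))
  print(x$summary)
  invisible(x)
}

#' Write realized adjacency to TSV
#'
#' One file per projection, columns `pre_gid`, `post_gid`, `receptor`,
#' `weight`.
#'
#' @param net A `cb_network`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_edges_tsv <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(net$edges)) {
    pr <- net$spec$projections[i, ]
    rc <- net$spec$receptors[net$spec$receptors$projection == pr$projection, ]
    geo <- net$geometry
    gpre <- geo[geo$population == pr$pre, ]
    gpost <- geo[geo$population == pr$post, ]
    e <- net$edges[[i]]
    n_per_pre <- diff(e$offsets)
    base <- tibble(
      pre_gid = rep.int(gpre$gid_base + seq_len(gpre$n_total) - 1L, n_per_pre),
      post_gid = gpost$gid_base + e$targets
    )
    rows <- bind_rows(lapply(seq_len(nrow(rc)), function(r) {
      mutate(base, receptor = rc$kind[r], weight = rc$weight[r])
    }))
    path <- file.path(dir, sprintf("edges_%s_%s.tsv", pr$pre, pr$post))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
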