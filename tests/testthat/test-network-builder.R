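test_that("placement is exact, in-bounds and deterministic", {
  spec <- cerebellar_tile_spec()
  s <- tiny_settings(100)
  pl <- place_populations(spec, s)
  expect_equal(sum(pl$population == "GR"), 819200L)
  expect_equal(sum(pl$population == "IO"), 1L)
  expect_true(all(pl$x >= 0 & pl$x < 1000))
  expect_true(all(pl$y >= 0 & pl$y < 1000))
  expect_true(all(diff(pl$gid[pl$population == "GR"]) == 1L))

  sp <- scale_tile_spec(spec, 1 / 64)
  s2 <- tiny_settings(100, tile_grid = c(2L, 2L))
  pl2 <- place_populations(sp, s2)
  per_tile <- sum(sp$layers$n_sheets * sp$layers$nx * sp$layers$ny)
  expect_equal(nrow(pl2), 4L * per_tile)
  expect_equal(unname(table(pl2$tile)), rep(per_tile, 4L), ignore_attr = TRUE)
  expect_identical(pl2, place_populations(sp, s2))
})

test_that("wiring is reproducible per seed and free of defects", {
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 64)
  s <- tiny_settings(100, seed = 9)
  net1 <- build_network(sp, s)
  net2 <- build_network(sp, s)
  for (nm in names(net1$edges)) {
    expect_identical(net1$edges[[nm]]$targets, net2$edges[[nm]]$targets,
                     info = nm)
  }
  net3 <- build_network(sp, tiny_settings(100, seed = 10))
  expect_false(identical(
    lapply(net1$edges, `[[`, "targets"),
    lapply(net3$edges, `[[`, "targets")
  ))

  # self-edges and duplicate pairs never occur (recurrent projections)
  sp16 <- scale_tile_spec(cerebellar_tile_spec(), 1 / 16)
  s16 <- tiny_settings(100, seed = 2, boundary = "periodic")
  for (nm in c("ST->ST", "BA->BA", "GO->GR", "GR->PC")) {
    ed <- realize_projection(sp16, s16, nm)
    expect_true(all(ed$pre_gid != ed$post_gid), info = nm)
    expect_false(any(duplicated(ed[, c("pre_gid", "post_gid")])), info = nm)
  }
})

test_that("connection frequency follows the Gaussian kernel law", {
  # pool pons->GR draws over seeds and compare binned connection frequency
  # with p_peak * exp(-d^2 / (2 sigma^2))
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 16)
  pl <- place_populations(sp, tiny_settings(100))
  pre <- pl[pl$population == "Pons", ]
  post <- pl[pl$population == "GR", ]
  pr <- sp$projections[sp$projections$projection == "Pons->GR", ]
  # candidate distances for a single interior pons cell
  p0 <- pre[which.min((pre$x - 500)^2 + (pre$y - 500)^2), ]
  d <- sqrt((post$x - p0$x)^2 + (post$y - p0$y)^2)
  cand <- which(d <= pr$cutoff_um)
  hits <- numeric(length(cand))
  n_seeds <- 6
  for (seed in seq_len(n_seeds)) {
    ed <- realize_projection(sp, tiny_settings(100, seed = seed), "Pons->GR")
    hits <- hits + as.numeric(post$gid[cand] %in% ed$post_gid[ed$pre_gid == p0$gid])
  }
  bins <- cut(d[cand], breaks = c(0, 20, 40, 60, 75))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    p_exp <- mean(pr$p * exp(-d[cand][idx]^2 / (2 * pr$sigma_um^2)))
    n <- length(idx) * n_seeds
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(sum(hits[idx]) / n - p_exp), 3.5 * max(se, 1e-3), label = b)
  }
})

test_that("realized synapse counts match the exact lattice expectation", {
  # every projection, three build seeds, z-score within 3 of the
  # deterministic sum of Bernoulli probabilities over the post lattice
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 16)
  s0 <- tiny_settings(100, boundary = "periodic")
  for (nm in sp$projections$projection) {
    oracle <- lattice_expected_count(sp, s0, nm)
    tot <- 0
    for (seed in 1:3) {
      ed <- realize_projection(sp, tiny_settings(100, seed = seed,
                                                 boundary = "periodic"), nm)
      tot <- tot + nrow(ed)
    }
    if (oracle$sd == 0) {
      expect_equal(tot, 3 * oracle$mean, label = nm)  # degenerate lattice
    } else {
      z <- (tot - 3 * oracle$mean) / (sqrt(3) * oracle$sd)
      expect_lt(abs(z), 3, label = sprintf("%s (z = %.2f)", nm, z))
    }
  }
})

test_that("interior mean degrees match the analytic kernel expectation", {
  # projections whose kernels are small against the (periodic) domain
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 16)
  cnt <- sapply(split(sp$layers$n_sheets * sp$layers$nx * sp$layers$ny,
                      sp$layers$population), sum)
  area <- 1e6
  for (nm in c("Pons->GR", "GR->ST", "GR->BA", "GR->PC", "GR->GO")) {
    pr <- sp$projections[sp$projections$projection == nm, ]
    rho <- cnt[[pr$post]] / area
    exp_deg <- if (pr$kernel == "gaussian") {
      expected_degree("gaussian", pr$p, rho, sigma = pr$sigma_um,
                      cutoff = pr$cutoff_um)
    } else {
      expected_degree("cross", pr$p, rho, pre_width = pr$pre_width_um,
                      post_width = pr$post_width_um)
    }
    n_pre <- cnt[[pr$pre]]
    tot <- 0
    for (seed in 4:6) {
      ed <- realize_projection(sp, tiny_settings(100, seed = seed,
                                                 boundary = "periodic"), nm)
      tot <- tot + nrow(ed)
    }
    emp <- tot / (3 * n_pre)
    se <- sqrt(exp_deg / (3 * n_pre))  # Poisson-scale error of the mean
    expect_lt(abs(emp - exp_deg), 3.5 * se,
              label = sprintf("%s: emp %.3f vs %.3f", nm, emp, exp_deg))
  }
  expect_equal(expected_degree("gaussian", 0, 1e-3, sigma = 100), 0)
  expect_equal(expected_degree("cross", 0, 1e-3, pre_width = 100,
                               post_width = 100), 0)
})

test_that("periodic wiring has no edge effects", {
  # out-degree of pres near the domain edge vs the center, same law
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 16)
  s <- tiny_settings(100, seed = 3, boundary = "periodic")
  pl <- place_populations(sp, s)
  pre <- pl[pl$population == "GO", ]
  degs <- integer(nrow(pre))
  for (seed in 1:3) {
    ed <- realize_projection(sp, tiny_settings(100, seed = seed,
                                               boundary = "periodic"),
                             "GO->GR")
    tab <- table(factor(ed$pre_gid, levels = pre$gid))
    degs <- degs + as.integer(tab)
  }
  edge_dist <- pmin(pre$x, 1000 - pre$x, pre$y, 1000 - pre$y)
  border <- edge_dist < 150
  expect_gt(stats::t.test(degs[border], degs[!border])$p.value, 0.01)
})

test_that("halo map is exactly the set of cross-tile edge sources", {
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 64)
  s <- tiny_settings(100, seed = 5, tile_grid = c(2L, 2L),
                     boundary = "periodic")
  net <- build_network(sp, s)
  pl <- net$placements
  tile_of <- stats::setNames(pl$tile, pl$gid)

  found <- list()
  for (nm in names(net$edges)) {
    ed <- realize_projection(sp, s, nm)
    pre_t <- tile_of[as.character(ed$pre_gid)]
    post_t <- tile_of[as.character(ed$post_gid)]
    cross <- pre_t != post_t
    if (any(cross)) {
      found[[nm]] <- tibble::tibble(from_tile = as.integer(pre_t[cross]),
                                    to_tile = as.integer(post_t[cross]),
                                    gid = ed$pre_gid[cross])
    }
  }
  want <- dplyr::arrange(dplyr::distinct(dplyr::bind_rows(found)),
                         from_tile, to_tile, gid)
  expect_equal(as.data.frame(net$halo), as.data.frame(want))

  # single open tile: no halo at all
  net1 <- build_network(sp, tiny_settings(100, seed = 5))
  expect_null(net1$halo)
})

test_that("adjacency dumps carry every synapse with its receptor and weight", {
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 64)
  net <- build_network(sp, tiny_settings(100, seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_edges_tsv(net, dir)
  gogr <- utils::read.table(file.path(dir, "edges_GO_GR.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(gogr),
               net$summary$n_synapses[net$summary$projection == "GO->GR"])
  expect_equal(unique(gogr$receptor), "GABA_A")
  w <- sp$receptors$weight[sp$receptors$projection == "GO->GR"]
  expect_equal(unique(gogr$weight), w)
  # dual-receptor projection doubles its rows
  grgo <- utils::read.table(file.path(dir, "edges_GR_GO.tsv"), header = TRUE,
                            sep = "\t")
  expect_equal(nrow(grgo),
               2 * net$summary$n_synapses[net$summary$projection == "GR->GO"])
  expect_setequal(unique(grgo$receptor), c("AMPA", "NMDA"))
})

test_that("cross-tile edges stay within the tile neighborhood", {
  sp <- scale_tile_spec(cerebellar_tile_spec(), 1 / 64)
  s <- tiny_settings(100, seed = 1, tile_grid = c(3L, 3L), boundary = "open")
  net <- build_network(sp, s)
  h <- net$halo
  fx <- h$from_tile %% 3L; fy <- h$from_tile %/% 3L
  tx <- h$to_tile %% 3L; ty <- h$to_tile %/% 3L
  expect_true(all(abs(fx - tx) <= 1 & abs(fy - ty) <= 1))
  expect_true(all(h$from_tile != h$to_tile))
})
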