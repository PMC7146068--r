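test_that("builtin tile spec reproduces every printed parameter", {
  spec <- cerebellar_tile_spec()

  counts <- sapply(split(spec$layers$n_sheets * spec$layers$nx * spec$layers$ny,
                         spec$layers$population), sum)
  expect_equal(counts[c("ST", "BA", "PC", "GR", "GO", "DCN", "IO", "Pons")],
               c(ST = 4096, BA = 1024, PC = 1024, GR = 819200, GO = 1024,
                 DCN = 1024, IO = 1, Pons = 1024))

  nn <- spec$neurons
  row <- function(p) nn[nn$population == p, ]
  pars <- list(  # tau_m, theta, v_reset, e_rest, i_ex, t_ref
    ST = c(10, -55, -70, -70, 0, 1), BA = c(10, -55, -70, -70, 0, 1),
    PC = c(10, -50, -70, -70, 22, 1), GR = c(7.2, -35, -70, -58, 0, 1),
    GO = c(12, -50, -70, -70, 0, 1), DCN = c(10, -40, -70, -70, 32, 1),
    IO = c(10, -50, -70, -70, 50, 1500), Pons = c(10, -50, -70, -70, 24, 1)
  )
  for (p in names(pars)) {
    r <- row(p)
    expect_equal(unname(unlist(r[c("tau_m", "theta", "v_reset", "e_rest",
                                   "i_ex", "t_ref")])),
                 pars[[p]], info = p)
  }

  pj <- function(nm) spec$projections[spec$projections$projection == nm, ]
  gauss <- list("GO->GR" = c(0.04, 200), "IO->PC" = c(1, 350),
                "Pons->GR" = c(1, 25))
  for (nm in names(gauss)) {
    expect_equal(c(pj(nm)$p, pj(nm)$sigma_um), gauss[[nm]], info = nm)
    expect_gte(pj(nm)$cutoff_um, 3 * pj(nm)$sigma_um)
  }
  cross <- list(  # pre_width, post_width, p
    "ST->ST" = c(50, 200, 0.02), "ST->PC" = c(50, 200, 0.1),
    "BA->BA" = c(50, 200, 0.02), "BA->PC" = c(50, 200, 0.1),
    "PC->BA" = c(50, 200, 0.05), "PC->DCN" = c(75, 600, 0.3),
    "GR->ST" = c(500, 100, 0.05), "GR->BA" = c(500, 100, 0.05),
    "GR->PC" = c(500, 100, 0.05), "GR->GO" = c(250, 100, 0.025)
  )
  for (nm in names(cross)) {
    expect_equal(c(pj(nm)$pre_width_um, pj(nm)$post_width_um, pj(nm)$p),
                 cross[[nm]], info = nm)
  }

  rc <- spec$receptors
  rw <- function(nm, kind) rc[rc$projection == nm & rc$kind == kind, ]
  weights <- list(
    c("ST->ST", "GABA_A", 2, 0.02), c("ST->PC", "GABA_A", 2, 0.05),
    c("BA->BA", "GABA_A", 2, 0.02), c("BA->PC", "GABA_A", 2, 0.1),
    c("PC->BA", "GABA_A", 2, 0.01), c("PC->DCN", "GABA_A", 2, 0.0025),
    c("GR->ST", "AMPA", 2, 0.00145), c("GR->BA", "AMPA", 2, 0.00145),
    c("GR->PC", "AMPA", 2, 0.0013), c("GR->GO", "AMPA", 2, 0.0008),
    c("GR->GO", "NMDA", 100, 0.00017), c("GO->GR", "GABA_A", 10, 3.0),
    c("IO->PC", "AMPA", 2, 0.1), c("Pons->GR", "AMPA", 2, 0.5)
  )
  for (w in weights) {
    r <- rw(w[1], w[2])
    expect_equal(nrow(r), 1L, info = paste(w[1], w[2]))
    expect_equal(c(r$tau_syn, r$weight), as.numeric(w[3:4]),
                 info = paste(w[1], w[2]))
  }

  # layer thicknesses (mm printed, um here), top to bottom
  th <- sapply(split(spec$layers$thickness_um, spec$layers$layer), max)
  expect_equal(th[c("molecular_upper", "molecular_lower", "pc_layer",
                    "granular", "dcn", "io", "pons")],
               c(molecular_upper = 100, molecular_lower = 100, pc_layer = 30,
                 granular = 200, dcn = 100, io = 100, pons = 200))
})

test_that("cross-kernel rectangles match the printed projection areas", {
  spec <- cerebellar_tile_spec()
  areas <- list(  # printed mediolateral x rostrocaudal extents of the pre cell
    "ST->ST" = c(100, 200), "ST->PC" = c(100, 200), "BA->BA" = c(100, 200),
    "BA->PC" = c(100, 200), "PC->BA" = c(100, 200), "PC->DCN" = c(150, 600),
    "GR->ST" = c(1000, 100), "GR->BA" = c(1000, 100), "GR->PC" = c(1000, 100),
    "GR->GO" = c(500, 100)
  )
  for (nm in names(areas)) {
    pr <- spec$projections[spec$projections$projection == nm, ]
    expect_equal(c(2 * pr$pre_width_um, pr$post_width_um), areas[[nm]],
                 info = nm)
  }
})

test_that("per-tile neuron totals give the full-array model size", {
  spec <- cerebellar_tile_spec()
  counts <- sapply(split(spec$layers$n_sheets * spec$layers$nx * spec$layers$ny,
                         spec$layers$population), sum)
  cerebellar <- sum(counts) - counts[["Pons"]]
  expect_equal(as.numeric(cerebellar), 827393)
})

test_that("OKR extension carries the printed NRTP/VN parameters", {
  spec <- okr_tile_spec()
  nr <- spec$neurons[spec$neurons$population == "NRTP", ]
  expect_equal(unname(unlist(nr[c("tau_m", "theta", "v_reset", "e_rest",
                                  "t_ref")])),
               c(40, -60, -70, -70, 1))
  pr <- spec$projections[spec$projections$projection == "NRTP->GR", ]
  expect_equal(c(pr$p, pr$sigma_um), c(0.1, 75))
  expect_equal(spec$neurons$i_ex[spec$neurons$population == "PC"], 24)
  expect_equal(spec$neurons$i_ex[spec$neurons$population == "VN"], 40)
  # VN reuses the DCN membrane row; PC->VN reuses the PC->DCN geometry
  vn <- spec$neurons[spec$neurons$population == "VN", ]
  dcn <- spec$neurons[spec$neurons$population == "DCN", ]
  expect_equal(vn[c("tau_m", "theta", "v_reset", "e_rest", "t_ref")],
               dcn[c("tau_m", "theta", "v_reset", "e_rest", "t_ref")],
               ignore_attr = TRUE)
  pv <- spec$projections[spec$projections$projection == "PC->VN", ]
  expect_equal(c(pv$pre_width_um, pv$post_width_um, pv$p), c(75, 600, 0.3))
  dr <- spec$drivers[spec$drivers$population == "NRTP", ]
  expect_equal(dr$mode, "sinusoid_current")
  expect_equal(dr$period_ms, 2000)
  expect_equal(validate_spec(spec), validate_spec(spec)[0, ],
               ignore_attr = TRUE)
})

test_that("settings parse applies defaults and flags bad input", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"duration": 2000, "tile_grid": [1, 1], "seed": 42}', f)
  s <- read_simulation_settings(f)
  expect_equal(s$dt, 0.1)
  expect_equal(s$boundary, "open")
  expect_equal(s$tile_size, 1000)
  expect_equal(s$seed, 42L)

  writeLines('{"duration": 0}', f)
  expect_error(read_simulation_settings(f), "duration")
  writeLines('{"dt": 0.1}', f)
  expect_error(read_simulation_settings(f), "duration")
  writeLines('{"duration": 100.05}', f)
  expect_error(read_simulation_settings(f), "multiple of dt")
  expect_error(simulation_settings(100, tile_grid = c(0, 1)), "tile_grid")
})

test_that("settings and network specs round-trip through JSON losslessly", {
  f <- withr::local_tempfile(fileext = ".json")
  s <- simulation_settings(2000, seed = 42L, tile_grid = c(2L, 3L),
                           warmup = 500, boundary = "periodic")
  write_simulation_settings(s, f)
  expect_equal(read_simulation_settings(f), s)

  for (spec in list(cerebellar_tile_spec(), okr_tile_spec())) {
    write_network_spec(spec, f)
    back <- read_network_spec(f)
    expect_equal(back, spec)
  }
})

test_that("network spec parse rejects malformed models", {
  f <- withr::local_tempfile(fileext = ".json")
  spec <- cerebellar_tile_spec()

  bad <- spec
  bad$projections$pre[1] <- "XX"
  write_network_spec(bad, f)
  expect_error(read_network_spec(f), "XX")

  bad <- spec
  bad$receptors$weight[2] <- -1
  write_network_spec(bad, f)
  expect_error(read_network_spec(f), "weight")

  bad <- spec
  bad$receptors$kind[1] <- "GABA_B"
  write_network_spec(bad, f)
  expect_error(read_network_spec(f), "GABA_B")

  # shipped defaults parse back to the builtins
  shipped <- system.file("extdata", "cerebellum.json", package = "cbsim")
  expect_true(nzchar(shipped))
  sp <- read_network_spec(shipped)
  expect_equal(sp, spec)
  counts <- sapply(split(sp$layers$n_sheets * sp$layers$nx * sp$layers$ny,
                         sp$layers$population), sum)
  expect_equal(counts[["GR"]], 819200)
  gogr <- sp$receptors[sp$receptors$projection == "GO->GR", ]
  expect_equal(gogr$tau_syn, 10)
})

test_that("validate_spec reports violations as data", {
  spec <- cerebellar_tile_spec()
  expect_equal(nrow(validate_spec(spec)), 0L)

  bad <- spec
  bad$projections$p[bad$projections$projection == "GO->GR"] <- 1.5
  v <- validate_spec(bad)
  expect_equal(nrow(v), 1L)
  expect_match(v$path, "GO->GR", fixed = TRUE)
  expect_match(v$constraint, "p <= 1")

  bad <- spec
  bad$receptors$tau_syn[1] <- 0
  v <- validate_spec(bad)
  expect_equal(nrow(v), 1L)
  expect_match(v$constraint, "tau_syn")
})

test_that("density scaling preserves expected synaptic drive", {
  spec <- cerebellar_tile_spec()
  expect_identical(scale_tile_spec(spec, 1), spec)
  expect_error(scale_tile_spec(spec, 0), "density_factor")
  expect_error(scale_tile_spec(spec, 1.5), "density_factor")

  sp <- scale_tile_spec(spec, 0.25)
  expect_equal(sp$layers$nx[sp$layers$population == "GR"], 160L)
  expect_equal(sp$layers$ny[sp$layers$population == "GR"], 160L)
  w_scaled <- sp$receptors$weight[sp$receptors$projection == "GR->PC"]
  w_full <- spec$receptors$weight[spec$receptors$projection == "GR->PC"]
  expect_equal(w_scaled, 4 * w_full)
  expect_equal(sp$layers$nx[sp$layers$population == "IO"], 1L)

  # expected in-degree x weight preserved within 5% for every projection
  area <- 1e6
  for (fac in c(0.25, 1 / 16)) {
    sp <- scale_tile_spec(spec, fac)
    for (i in seq_len(nrow(spec$projections))) {
      pr <- spec$projections[i, ]
      deg_w <- function(s) {
        cnt <- sapply(split(s$layers$n_sheets * s$layers$nx * s$layers$ny,
                            s$layers$population), sum)
        rho_pre <- cnt[[pr$pre]] / area
        deg_in <- if (pr$kernel == "gaussian") {
          expected_degree("gaussian", pr$p, rho_pre, sigma = pr$sigma_um,
                          cutoff = pr$cutoff_um)
        } else {
          expected_degree("cross", pr$p, rho_pre, pre_width = pr$pre_width_um,
                          post_width = pr$post_width_um)
        }
        w <- s$receptors$weight[s$receptors$projection == pr$projection][1]
        deg_in * w
      }
      expect_lt(abs(deg_w(sp) / deg_w(spec) - 1), 0.05,
                label = sprintf("%s at factor %.3g", pr$projection, fac))
    }
  }
})
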