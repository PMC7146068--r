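#' Simulation settings
#'
#' Construct the run-level settings object: biological duration, integration
#' step, tile layout, boundary handling and the master seed. All lengths are in
#' micrometers and all times in milliseconds.
#'
#' @param duration Simulated biological time (ms). Must be a positive multiple
#'   of `dt`.
#' @param dt Integration time step (ms). The model is defined at 0.1 ms.
#' @param tile_grid Integer pair: number of 1-tile columns and rows along x
#'   and y.
#' @param tile_size Side of a (square) tile in micrometers.
#' @param seed Master seed; all wiring and driver randomness derives from it.
#' @param warmup Initial period (ms) excluded from analysis windows.
#' @param output_dir Optional directory for file output; `NULL` keeps results
#'   in memory only.
#' @param boundary `"open"` (kernels truncate at the edge of the tile array) or
#'   `"periodic"` (minimal-image wrap-around, emulating an interior tile).
#' @param n_workers Nominal worker count recorded with the run. Execution is
#'   sequential and results never depend on this value.
#' @return A `cb_settings` list.
#' @examples
#' s <- simulation_settings(duration = 1000, seed = 42)
#' s$dt
#' @export
simulation_settings <- function(duration,
                                dt = 0.1,
                                tile_grid = c(1L, 1L),
                                tile_size = 1000,
                                seed = 1L,
                                warmup = 0,
                                output_dir = NULL,
                                boundary = c("open", "periodic"),
                                n_workers = 1L) {
  boundary <- match.arg(boundary)
  s <- structure(
    list(
      duration = as.numeric(duration),
      dt = as.numeric(dt),
      tile_grid = as.integer(tile_grid),
      tile_size = as.numeric(tile_size),
      seed = as.integer(seed),
      warmup = as.numeric(warmup),
      output_dir = output_dir,
      boundary = boundary,
      n_workers = as.integer(n_workers)
    ),
    class = "cb_settings"
  )
  .check_settings(s)
  s
}

.check_settings <- function(s) {
  if (!is.finite(s$dt) || s$dt <= 0) {
    abort(sprintf("validation error: dt must be > 0 (got %s)", s$dt))
  }
  if (!is.finite(s$duration) || s$duration <= 0) {
    abort(sprintf("validation error: duration must be > 0 (got %s)", s$duration))
  }
  nsteps <- s$duration / s$dt
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    abort(sprintf("validation error: duration (%s ms) is not a multiple of dt (%s ms)",
                  s$duration, s$dt))
  }
  if (length(s$tile_grid) != 2L || any(is.na(s$tile_grid)) || any(s$tile_grid < 1L)) {
    abort("validation error: tile_grid must be two integers >= 1")
  }
  if (!is.finite(s$tile_size) || s$tile_size <= 0) {
    abort("validation error: tile_size must be > 0")
  }
  if (s$warmup < 0 || s$warmup >= s$duration) {
    abort("validation error: warmup must lie in [0, duration)")
  }
  if (s$n_workers < 1L) abort("validation error: n_workers must be >= 1")
  invisible(s)
}

#' Read and write simulation settings as JSON
#'
#' The on-disk format is a flat JSON object with the fields of
#' [simulation_settings()]. Unspecified optional fields take the documented
#' defaults (`dt = 0.1`, `boundary = "open"`, ...). A missing mandatory key
#' (`duration`) is a configuration error.
#'
#' @param path File path.
#' @return `read_simulation_settings()` returns a `cb_settings` object;
#'   `write_simulation_settings()` returns `path` invisibly.
#' @export
read_simulation_settings <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration error: no such file '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("duration")) {
    if (is.null(j[[key]])) {
      abort(sprintf("configuration error: missing mandatory key '%s'", key))
    }
  }
  simulation_settings(
    duration = j$duration,
    dt = j$dt %||% 0.1,
    tile_grid = j$tile_grid %||% c(1L, 1L),
    tile_size = j$tile_size %||% 1000,
    seed = j$seed %||% 1L,
    warmup = j$warmup %||% 0,
    output_dir = j$output_dir,
    boundary = j$boundary %||% "open",
    n_workers = j$n_workers %||% 1L
  )
}

#' @rdname read_simulation_settings
#' @param settings A `cb_settings` object.
#' @export
write_simulation_settings <- function(settings, path) {
  stopifnot(inherits(settings, "cb_settings"))
  x <- unclass(settings)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.cb_settings <- function(x, ...) {
  cat(sprintf(
    "<cb_settings> %g ms @ dt %g ms | %d x %d tiles of %g um | boundary %s | seed %d\n",
    x$duration, x$dt, x$tile_grid[1], x$tile_grid[2], x$tile_size, x$boundary, x$seed
  ))
  invisible(x)
}
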