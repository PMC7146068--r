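#' Read and write a tile model specification as JSON
#'
#' The network file is a JSON object with five arrays — `layers`, `neurons`,
#' `projections`, `receptors`, `drivers` — whose records mirror the columns of
#' the corresponding [cb_spec] tibbles. A parsed spec is always validated;
#' writing then re-reading a valid spec reproduces it exactly. `GABA_B` is a
#' recognized receptor name in the literature but has no parameters in this
#' model and is rejected at parse time.
#'
#' @param path File path.
#' @return `read_network_spec()` returns a validated [cb_spec];
#'   `write_network_spec()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_network_spec(cerebellar_tile_spec(), f)
#' spec <- read_network_spec(f)
#' @export
read_network_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("configuration error: no such file '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("layers", "neurons", "projections", "receptors", "drivers")) {
    if (is.null(j[[key]])) {
      abort(sprintf("configuration error: missing mandatory key '%s'", key))
    }
  }
  if (any(j$receptors$kind == "GABA_B")) {
    abort("validation error: GABA_B receptors are not supported by this model")
  }

  int_cols <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
    df
  }
  opt_cols <- function(df, cols) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA_real_
    for (cc in cols) df[[cc]] <- as.numeric(df[[cc]])  # all-null reads as logical
    df
  }

  layers <- as_tibble(int_cols(j$layers, c("n_sheets", "nx", "ny")))
  neurons <- as_tibble(j$neurons)
  projections <- as_tibble(opt_cols(j$projections,
    c("sigma_um", "cutoff_um", "pre_width_um", "post_width_um")))
  projections <- projections[, c("projection", "pre", "post", "kernel", "p",
                                 "sigma_um", "cutoff_um",
                                 "pre_width_um", "post_width_um")]
  receptors <- as_tibble(j$receptors)
  drivers <- as_tibble(opt_cols(j$drivers,
    c("rate_hz", "amplitude", "period_ms", "phase")))
  drivers <- drivers[, c("population", "mode", "rate_hz", "amplitude",
                         "period_ms", "phase")]

  spec <- .new_spec(layers, neurons, projections, receptors, drivers)
  .assert_valid_spec(spec)
  spec
}

#' @rdname read_network_spec
#' @param spec A [cb_spec].
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cb_spec"))
  jsonlite::write_json(
    lapply(unclass(spec), as.data.frame),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  invisible(path)
}
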