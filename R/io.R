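#' Write / read a configuration as YAML
#'
#' Serializes a [lyo_config()] to a structured-text (YAML) file with the
#' sections formulation / vial / thermo / transport / desorption /
#' nucleation / freezing / primary / secondary / numerics. Piecewise-linear
#' protocol channels are stored as `{time: [...], value: [...]}` tables and
#' restored on read. Derived quantities are recomputed on read, so
#' `read_config(write_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A `lyo_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `lyo_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "lyo_config"))
  x <- unclass(cfg)
  x$derived <- NULL
  ser <- lapply(x, function(sec) {
    lapply(sec, function(v) {
      if (inherits(v, "protocol_channel")) {
        list(piecewise = list(time = v$time, value = v$value))
      } else v
    })
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x <- lapply(x, function(sec) {
    lapply(sec, function(v) {
      if (is.list(v) && identical(names(v), "piecewise")) {
        protocol_channel(v$piecewise$time, v$piecewise$value)
      } else v
    })
  })
  do.call(lyo_config, x)
}

#' Write simulation outputs to a directory
#'
#' Writes the tabular trajectory/summary of a stage result (or all stages of
#' a cycle result) as CSV, plus a JSON manifest with the stage timestamps,
#' schema version and the seed used.
#'
#' @param result A `lyo_freezing`, `lyo_primary`, `lyo_secondary` or
#'   `lyo_cycle` object.
#' @param dir Output directory (created if missing).
#' @param seed Seed to record in the manifest (optional).
#' @return The manifest (invisibly).
#' @export
write_outputs <- function(result, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(schema = "lyosim-1", class = class(result)[1],
                   seed = seed, created = format(Sys.time(), tz = "UTC"))
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  if (inherits(result, "lyo_freezing")) {
    wcsv(result$trajectory, "freezing_trajectory.csv")
    manifest$times <- result$times
    manifest$evaporated_kg <- result$evaporated
  } else if (inherits(result, "lyo_primary")) {
    wcsv(result$summary, "primary_summary.csv")
    wcsv(primary_field(result), "primary_field.csv")
    manifest$t_d1 <- result$t_d1
  } else if (inherits(result, "lyo_secondary")) {
    wcsv(result$summary, "secondary_summary.csv")
    manifest$t_d2 <- result$t_d2
  } else if (inherits(result, "lyo_cycle")) {
    wcsv(result$freezing$trajectory, "freezing_trajectory.csv")
    wcsv(result$primary$summary, "primary_summary.csv")
    wcsv(result$secondary$summary, "secondary_summary.csv")
    manifest$summary <- as.list(result$summary)
  } else {
    stop("unsupported result class", call. = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
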