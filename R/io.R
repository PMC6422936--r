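#' Write / read track tables as CSV
#'
#' Tracks are stored in the shared schema (`cell_id`, `frame`, `t_min`,
#' `x_um`, `y_um`, and `region` when present).  A provenance header is
#' written as `#`-prefixed comment lines (preset label and hash, condition,
#' seed, package version) and skipped transparently on read.
#'
#' @param tracks track `data.frame` or `muc3_run`.
#' @param path CSV file path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()`
#'   returns the track `data.frame` with the provenance header (if any) in
#'   the `"provenance"` attribute.
#' @export
write_tracks <- function(tracks, path) {
  header <- character(0)
  if (inherits(tracks, "muc3_run")) {
    header <- c(
      sprintf("# preset: %s (hash %s)", tracks$preset$label, tracks$preset_hash),
      sprintf("# condition: %s", tracks$condition),
      sprintf("# n_cells: %d, duration_min: %g, dt_min: %g, seed: %d",
              tracks$n_cells, tracks$duration, tracks$dt, tracks$seed),
      sprintf("# muc3 version: %s", as.character(utils::packageVersion("muc3"))))
    tracks <- tracks$tracks
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.csv(tracks, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  lines <- readLines(path, n = 20)
  n_hdr <- sum(cumprod(startsWith(lines, "#")))
  out <- utils::read.csv(path, skip = n_hdr, stringsAsFactors = FALSE)
  if (n_hdr) attr(out, "provenance") <- sub("^# ?", "", lines[seq_len(n_hdr)])
  out
}

#' Write / read an experiment configuration as YAML
#'
#' Serialises the device geometry, the chemoattractant pair and a preset so
#' a run can be reproduced from a plain-text file.
#'
#' @param geometry a [device_geometry()].
#' @param attractants named list of [chemoattractant_spec()]s (or `NULL` for
#'   a no-chemoattractant configuration).
#' @param preset a [priming_preset()].
#' @param run list of run settings (`n_cells`, `duration`, `dt`, `seed`).
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a list with `geometry`, `attractants`, `preset`, `run`.
#' @export
write_config <- function(geometry, attractants, preset, run, path) {
  cfg <- list(
    geometry = unclass(geometry)[c("channel_length", "channel_width",
                                   "n_channels", "channel_pitch",
                                   "loading_width", "reservoir_depth",
                                   "rung_positions", "maze_attenuation")],
    attractants = if (is.null(attractants)) NULL else
      lapply(attractants, unclass),
    preset = unclass(preset),
    run = run)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geometry <- do.call(device_geometry, cfg$geometry)
  attractants <- if (!is.null(cfg$attractants))
    lapply(cfg$attractants, function(a) do.call(chemoattractant_spec, a))
  preset <- do.call(priming_preset, cfg$preset)
  list(geometry = geometry, attractants = attractants, preset = preset,
       run = cfg$run)
}
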