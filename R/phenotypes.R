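## Helpers shared by the metric functions -----------------------------------

as_tracks <- function(x) {
  if (inherits(x, "muc3_run")) return(x$tracks)
  stopifnot(is.data.frame(x),
            all(c("cell_id", "frame", "t_min", "x_um", "y_um") %in% names(x)))
  x
}

region_selector <- function(which) {
  switch(which,
         reservoir_fmlp = "reservoir_fmlp",
         reservoir_ltb4 = "reservoir_ltb4",
         channels_fmlp = c("channel_fmlp", "maze_fmlp"),
         channels_ltb4 = c("channel_ltb4", "maze_ltb4"),
         channels = c("channel_fmlp", "maze_fmlp", "channel_ltb4", "maze_ltb4"),
         reservoirs = c("reservoir_fmlp", "reservoir_ltb4"),
         stop("unknown region selector: ", which))
}

#' Annotate track samples with their device region
#'
#' Labels every sample of a track table by the region containing it, using
#' the geometry lookup.  Boundary samples resolve toward the region more
#' distal from the loading channel (mouth -> channel, reservoir mouth ->
#' reservoir, channel/rung junction -> rung).  Positions outside the device
#' raise an error.
#'
#' @param tracks a track `data.frame` (or a `muc3_run`).
#' @param geometry a [device_geometry()].
#' @param snap tolerance (um) within which positions slightly outside any
#'   region (e.g. tracked centroids with localisation noise) are snapped to
#'   the nearest structure; 0 (default) requires exact containment.
#' @return The track table with a (re)computed `region` column.
#' @export
assign_regions <- function(tracks, geometry = device_geometry(), snap = 0) {
  tr <- as_tracks(tracks)
  tr$region <- point_region(geometry, tr$x_um, tr$y_um, snap = snap)
  tr
}

#' Percent-migrated time series
#'
#' For each frame, the number of cells in the selected region divided by the
#' time-averaged number of cells in the central loading channel over the
#' whole experiment, times 100.  The denominator deliberately averages over
#' *all* frames (including frames after cells have emigrated), following the
#' metric's definition.  With `cumulative = TRUE` a cell counts from the
#' first frame at which it has ever visited the selected region (used for
#' spontaneous migration into the channels).
#'
#' @param tracks track table or `muc3_run`; must carry a `region` column.
#' @param region one of `"reservoir_fmlp"`, `"reservoir_ltb4"`,
#'   `"channels_fmlp"`, `"channels_ltb4"`, `"channels"`, `"reservoirs"`.
#' @param cumulative count cells ever seen in the region up to each frame.
#' @return `data.frame` with columns `t_min` and `percent`.
#' @export
percent_migrated_series <- function(tracks, region = "reservoir_fmlp",
                                    cumulative = FALSE) {
  tr <- as_tracks(tracks)
  if (!nrow(tr)) stop("empty track table")
  if (is.null(tr$region)) stop("tracks must carry region annotations")
  frames <- sort(unique(tr$frame))
  t_min <- tapply(tr$t_min, tr$frame, function(v) v[1])[as.character(frames)]
  load_n <- tapply(tr$region == "loading", tr$frame, sum)[as.character(frames)]
  denom <- mean(load_n)
  if (denom == 0)
    stop("undefined denominator: no cells in the loading channel at any frame")
  sel <- tr$region %in% region_selector(region)
  if (cumulative) {
    # first frame at which each cell has visited the region
    hit <- tr[sel, c("cell_id", "frame")]
    if (nrow(hit)) {
      first <- tapply(hit$frame, hit$cell_id, min)
      counts <- vapply(frames, function(f) sum(first <= f), numeric(1))
    } else counts <- rep(0, length(frames))
  } else {
    counts <- as.numeric(tapply(sel, tr$frame, sum)[as.character(frames)])
  }
  data.frame(t_min = as.numeric(t_min), percent = 100 * counts / denom)
}

#' Maximum hourly rate of accumulation
#'
#' Ordinary least-squares slope of the percent-migrated series computed in
#' every sliding window of length `window` aligned to the frame grid; the
#' maximum over windows is returned, expressed per hour: the slope of the
#' hour during which cells accumulated fastest.
#'
#' @param series `data.frame` with `t_min` and `percent`
#'   (from [percent_migrated_series()]).
#' @param window window length (min), default 60.
#' @return Maximum slope in percent per hour.
#' @export
rate_of_accumulation <- function(series, window = 60) {
  stopifnot(is.data.frame(series), all(c("t_min", "percent") %in% names(series)))
  t <- series$t_min; p <- series$percent
  span <- diff(range(t))
  if (span < window) stop("series shorter than the rate window")
  dt <- diff(t)[1]
  nw <- round(window / dt)               # samples per window minus one
  n <- length(t)
  slopes <- vapply(seq_len(n - nw), function(i) {
    ti <- t[i:(i + nw)]; pi <- p[i:(i + nw)]
    sum((ti - mean(ti)) * (pi - mean(pi))) / sum((ti - mean(ti))^2)
  }, numeric(1))
  max(slopes) * 60                        # %/min -> %/h
}

#' Single-cell migration velocity
#'
#' Total path length divided by elapsed time, over the samples in scope.
#' The default `"in_channel"` scope restricts to consecutive sample pairs in
#' which both samples lie in a migration channel or maze rung on the same
#' side, i.e. the velocity *toward* that side's chemoattractant;
#' `"whole_track"` uses every consecutive pair.
#'
#' @param track track table rows of a single cell, ordered by frame, with a
#'   `region` column.
#' @param scope `"in_channel"` (default) or `"whole_track"`.
#' @return Velocity in um/min, or `NA` (with a `"muc3_short_track"`
#'   condition message suppressed-by-default) when fewer than two samples
#'   are in scope.
#' @export
cell_velocity <- function(track, scope = c("in_channel", "whole_track")) {
  scope <- match.arg(scope)
  track <- track[order(track$frame), ]
  if (nrow(track) < 2) return(NA_real_)
  dx <- diff(track$x_um); dy <- diff(track$y_um); dt <- diff(track$t_min)
  seg <- sqrt(dx^2 + dy^2)
  # use single-frame segments only: a straight line bridged across a
  # detection gap under-measures the path actually travelled
  keep <- dt <= 1.5 * min(dt[dt > 0])
  if (scope == "in_channel") {
    side_of <- function(r) ifelse(grepl("fmlp$", r), 1L,
                                  ifelse(grepl("ltb4$", r), 2L, 0L))
    in_ch <- track$region %in% c("channel_fmlp", "channel_ltb4",
                                 "maze_fmlp", "maze_ltb4")
    sd1 <- side_of(track$region)
    keep <- keep & in_ch[-length(in_ch)] & in_ch[-1] &
      sd1[-length(sd1)] == sd1[-1]
  }
  seg <- seg[keep]; dt <- dt[keep]
  if (length(seg) < 1 || sum(dt) <= 0) return(NA_real_)
  sum(seg) / sum(dt)
}

#' Per-cell velocity table
#'
#' Applies [cell_velocity()] to every cell and labels each with the side
#' (fMLP or LTB4) whose channels it visited first.  Cells with fewer than
#' two in-scope samples are excluded.
#'
#' @param tracks track table or `muc3_run` with region annotations.
#' @param scope passed to [cell_velocity()].
#' @param min_path minimum in-scope path length (um) for a cell to count as
#'   migrating; shorter excursions (e.g. a cell peeking into a channel
#'   mouth) are excluded from velocity summaries.
#' @return `data.frame` with `cell_id`, `side` (`"fmlp"`, `"ltb4"` or `NA`),
#'   `velocity_um_min`.
#' @export
velocity_table <- function(tracks, scope = "in_channel", min_path = 20) {
  tr <- as_tracks(tracks)
  by_cell <- split(tr, tr$cell_id)
  side_first <- function(d) {
    m <- regmatches(d$region, regexpr("(fmlp|ltb4)$", d$region))
    if (length(m)) m[1] else NA_character_
  }
  path_len <- function(d) {
    d <- d[order(d$frame), ]
    if (nrow(d) < 2) return(0)
    seg <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    if (scope == "in_channel") {
      in_ch <- d$region %in% c("channel_fmlp", "channel_ltb4",
                               "maze_fmlp", "maze_ltb4")
      seg <- seg[in_ch[-length(in_ch)] & in_ch[-1]]
    }
    sum(seg)
  }
  out <- data.frame(
    cell_id = as.integer(names(by_cell)),
    side = vapply(by_cell, side_first, character(1)),
    velocity_um_min = vapply(by_cell, cell_velocity, numeric(1), scope = scope),
    path_um = vapply(by_cell, path_len, numeric(1)))
  out <- out[!is.na(out$velocity_um_min) & out$path_um >= min_path, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count direction changes of a track
#'
#' Per-axis step displacements smaller than `jitter_threshold` in magnitude
#' are ignored on that axis; a direction change is a sign flip between
#' consecutive retained steps on x or on y.  The total number of flips over
#' both axes is returned.
#'
#' @param track single-cell track table ordered by frame.
#' @param jitter_threshold noise floor (um), default 2 (below half a channel
#'   width, so lateral centroid jitter does not register as a turn).
#' @return Integer count (0 for tracks shorter than 3 samples).
#' @export
count_direction_changes <- function(track, jitter_threshold = 2) {
  track <- track[order(track$frame), ]
  if (nrow(track) < 3) return(0L)
  flips <- function(d) {
    d <- d[abs(d) >= jitter_threshold]
    if (length(d) < 2) return(0L)
    sum(sign(d[-1]) != sign(d[-length(d)]))
  }
  flips(diff(track$x_um)) + flips(diff(track$y_um))
}

#' Classify a track's migratory phenotype
#'
#' Non-exclusive flags: `non_directional` when the cell entered a maze rung
#' at any point (a "lost" cell), `oscillatory` when it changed direction at
#' least 3 times ([count_direction_changes()]), and `directional` when it
#' left the loading channel and neither of the other flags is set.
#'
#' @param track single-cell track table with region annotations.
#' @param geometry a [device_geometry()] (used to recompute regions when the
#'   track lacks them).
#' @param jitter_threshold passed to [count_direction_changes()].
#' @return `data.frame` with columns `directional`, `non_directional`,
#'   `oscillatory`, `side`, `n_direction_changes`.
#' @export
classify_track <- function(track, geometry = device_geometry(),
                           jitter_threshold = 2) {
  if (is.null(track$region)) track <- assign_regions(track, geometry)
  track <- track[order(track$frame), ]
  non_dir <- any(track$region %in% c("maze_fmlp", "maze_ltb4"))
  ndc <- count_direction_changes(track, jitter_threshold)
  osc <- ndc >= 3L
  left <- any(track$region != "loading")
  m <- regmatches(track$region, regexpr("(fmlp|ltb4)$", track$region))
  data.frame(directional = left && !non_dir && !osc,
             non_directional = non_dir,
             oscillatory = osc,
             side = if (length(m)) m[1] else NA_character_,
             n_direction_changes = ndc)
}

#' Decision ratio: fMLP over LTB4
#'
#' Final percent migrated toward the fMLP reservoir divided by final percent
#' toward the LTB4 reservoir.  With a zero denominator the ratio is `Inf`
#' and the `"undefined"` attribute is set; with both endpoints zero it is
#' `NaN` with the same flag.
#'
#' @param metrics a `muc3_metrics` object (see [migration_metrics()]), or a
#'   numeric endpoint percent toward fMLP (then `ltb4` must be given).
#' @param ltb4 endpoint percent toward LTB4 when `metrics` is numeric.
#' @return Dimensionless ratio.
#' @export
decision_ratio <- function(metrics, ltb4 = NULL) {
  if (inherits(metrics, "muc3_metrics")) {
    pf <- metrics$endpoint_pct["reservoir_fmlp"]
    pl <- metrics$endpoint_pct["reservoir_ltb4"]
  } else {
    pf <- metrics; pl <- ltb4
    stopifnot(is.numeric(pf), is.numeric(pl))
  }
  if (pl == 0) {
    out <- if (pf == 0) NaN else Inf
    attr(out, "undefined") <- TRUE
    return(out)
  }
  unname(pf / pl)
}

#' Spontaneous migration fraction
#'
#' Percentage of cells that entered a migration channel (or maze rung) at
#' any time during a no-chemoattractant run, with the same time-averaged
#' loading-channel denominator as [percent_migrated_series()], reported at
#' the end of the run.
#'
#' @param run a `muc3_run` with `condition == "no_chemoattractant"`.
#' @return Percentage.
#' @export
spontaneous_fraction <- function(run) {
  stopifnot(inherits(run, "muc3_run"))
  if (run$condition != "no_chemoattractant")
    stop("spontaneous_fraction() requires a no-chemoattractant run")
  s <- percent_migrated_series(run, "channels", cumulative = TRUE)
  s$percent[nrow(s)]
}

#' Full migration metric suite for one run
#'
#' Computes the complete per-condition summary: percent-migrated series and
#' endpoint percentages per reservoir, maximum hourly accumulation rates,
#' per-cell velocities by side, classification counts (directional,
#' non-directional/"lost", oscillatory) by side, and the decision ratio.
#'
#' @param run a `muc3_run`, or a region-annotated track table.
#' @param jitter_threshold passed to [classify_track()].
#' @param rate_window passed to [rate_of_accumulation()].
#' @return An object of class `muc3_metrics`.
#' @export
migration_metrics <- function(run, jitter_threshold = 2, rate_window = 60) {
  tr <- as_tracks(run)
  series <- list(
    reservoir_fmlp = percent_migrated_series(tr, "reservoir_fmlp"),
    reservoir_ltb4 = percent_migrated_series(tr, "reservoir_ltb4"))
  endpoint <- vapply(series, function(s) s$percent[nrow(s)], numeric(1))
  rates <- vapply(series, function(s)
    if (diff(range(s$t_min)) >= rate_window)
      rate_of_accumulation(s, rate_window) else NA_real_, numeric(1))
  vel <- velocity_table(tr, scope = "in_channel")
  cls <- do.call(rbind, lapply(split(tr, tr$cell_id), classify_track,
                               jitter_threshold = jitter_threshold))
  cls$cell_id <- as.integer(names(split(tr, tr$cell_id)))
  counts <- function(flag) c(
    fmlp = sum(cls[[flag]] & cls$side %in% "fmlp"),
    ltb4 = sum(cls[[flag]] & cls$side %in% "ltb4"))
  m <- list(series = series,
            endpoint_pct = endpoint,
            rate_pct_per_h = rates,
            velocities = vel,
            velocity_mean = c(
              fmlp = mean(vel$velocity_um_min[vel$side %in% "fmlp"]),
              ltb4 = mean(vel$velocity_um_min[vel$side %in% "ltb4"])),
            classification = cls,
            n_directional = counts("directional"),
            n_lost = counts("non_directional"),
            n_oscillatory = counts("oscillatory"),
            decision_ratio = decision_ratio(endpoint[["reservoir_fmlp"]],
                                            endpoint[["reservoir_ltb4"]]),
            condition = if (inherits(run, "muc3_run")) run$condition else NA,
            spontaneous_pct = if (inherits(run, "muc3_run") &&
                                  run$condition == "no_chemoattractant")
              spontaneous_fraction(run) else NA_real_)
  class(m) <- "muc3_metrics"
  m
}

#' @export
print.muc3_metrics <- function(x, ...) {
  cat("<muc3_metrics>\n")
  cat(sprintf("  endpoint %%: fMLP %.2f, LTB4 %.2f (ratio %.2f)\n",
              x$endpoint_pct[["reservoir_fmlp"]],
              x$endpoint_pct[["reservoir_ltb4"]], x$decision_ratio))
  cat(sprintf("  max 1-h rate (%%/h): fMLP %.2f, LTB4 %.2f\n",
              x$rate_pct_per_h[["reservoir_fmlp"]],
              x$rate_pct_per_h[["reservoir_ltb4"]]))
  cat(sprintf("  mean in-channel velocity (um/min): fMLP %.2f (n=%d), LTB4 %.2f (n=%d)\n",
              x$velocity_mean[["fmlp"]], sum(x$velocities$side %in% "fmlp"),
              x$velocity_mean[["ltb4"]], sum(x$velocities$side %in% "ltb4")))
  cat(sprintf("  lost: %d/%d; oscillatory: %d/%d; directional: %d/%d (fMLP/LTB4)\n",
              x$n_lost[["fmlp"]], x$n_lost[["ltb4"]],
              x$n_oscillatory[["fmlp"]], x$n_oscillatory[["ltb4"]],
              x$n_directional[["fmlp"]], x$n_directional[["ltb4"]]))
  if (!is.na(x$spontaneous_pct))
    cat(sprintf("  spontaneous migration: %.2f %%\n", x$spontaneous_pct))
  invisible(x)
}

#' Plot percent-migrated series of a metrics object
#'
#' @param x a `muc3_metrics`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.muc3_metrics <- function(x, ...) {
  sf <- x$series$reservoir_fmlp; sl <- x$series$reservoir_ltb4
  graphics::plot(sf$t_min, sf$percent, type = "l", col = "darkgreen",
                 xlab = "time (min)", ylab = "% migrated",
                 ylim = range(0, sf$percent, sl$percent), ...)
  graphics::lines(sl$t_min, sl$percent, col = "firebrick")
  graphics::legend("topleft", c("fMLP reservoir", "LTB4 reservoir"),
                   col = c("darkgreen", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
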