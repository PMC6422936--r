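#' Coordinate model of the competitive chemotaxis chip
#'
#' Builds the device geometry: a central cell-loading channel, `n_channels`
#' straight migration channels per side running to a chemoattractant
#' reservoir at each end, and vertical maze ("ladder") rungs connecting
#' adjacent migration channels at fixed axial positions.  The origin is at
#' the centre of the loading channel; +x points toward the fMLP reservoir
#' and -x toward the LTB4 reservoir.  All lengths are micrometres.
#'
#' @param channel_length length of each migration channel (um).
#' @param channel_width channel width (um); channels have a square
#'   cross-section so this is also their depth.
#' @param n_channels number of migration channels per side.
#' @param channel_pitch centre-to-centre spacing of adjacent channels (um).
#' @param loading_width x-extent of the central loading channel (um).
#' @param reservoir_depth x-extent of each chemoattractant reservoir (um).
#' @param rung_positions axial positions (um, measured from the
#'   loading-channel mouth) where maze rungs join adjacent channels.
#' @param maze_attenuation factor by which the chemoattractant gradient in a
#'   maze rung is weaker than in the straight channels.
#' @return An object of class `muc3_geometry`.
#' @examples
#' geom <- device_geometry()
#' geom
#' @export
device_geometry <- function(channel_length = 900,
                            channel_width = 10,
                            n_channels = 10,
                            channel_pitch = 60,
                            loading_width = 100,
                            reservoir_depth = 200,
                            rung_positions = c(150, 300, 450, 600, 750),
                            maze_attenuation = 10) {
  stopifnot(channel_length > 0, channel_width > 0, n_channels >= 1,
            channel_pitch > channel_width, loading_width > 0,
            reservoir_depth > 0, maze_attenuation >= 1)
  if (length(rung_positions) &&
      any(rung_positions <= channel_width / 2 |
          rung_positions >= channel_length - channel_width / 2))
    stop("rung_positions must lie strictly inside the migration channels")
  yc <- (seq_len(n_channels) - (n_channels + 1) / 2) * channel_pitch
  g <- list(
    channel_length   = channel_length,
    channel_width    = channel_width,
    n_channels       = n_channels,
    channel_pitch    = channel_pitch,
    loading_width    = loading_width,
    reservoir_depth  = reservoir_depth,
    rung_positions   = sort(rung_positions),
    maze_attenuation = maze_attenuation,
    channel_centers_y = yc,
    # loading channel spans the full bank of channels plus half a pitch
    loading_half_height = max(abs(yc)) + channel_pitch / 2,
    mouth_x = loading_width / 2,
    reservoir_mouth_x = loading_width / 2 + channel_length
  )
  class(g) <- "muc3_geometry"
  g
}

#' @export
print.muc3_geometry <- function(x, ...) {
  cat("<muc3_geometry>\n")
  cat(sprintf("  %d migration channels/side, %g x %g um cross-section, %g um long\n",
              x$n_channels, x$channel_width, x$channel_width, x$channel_length))
  cat(sprintf("  loading channel %g um wide, reservoirs %g um deep\n",
              x$loading_width, x$reservoir_depth))
  cat(sprintf("  %d maze rungs/channel pair at x = %s um from the mouth (gradient 1/%g)\n",
              length(x$rung_positions),
              paste(x$rung_positions, collapse = ", "), x$maze_attenuation))
  invisible(x)
}

## Region codes shared by the simulator, the tracker and the metrics.
muc3_regions <- c("loading",
                  "channel_fmlp", "channel_ltb4",
                  "maze_fmlp", "maze_ltb4",
                  "reservoir_fmlp", "reservoir_ltb4")

## Vectorised point -> region lookup.  Boundary points are resolved toward
## the region more distal from the loading channel: the channel mouth
## belongs to the channel, the reservoir mouth to the reservoir, and the
## channel/rung junction line to the rung.
point_region <- function(geometry, x, y, allow_outside = FALSE, snap = 0) {
  out <- point_region_strict(geometry, x, y)
  if (snap > 0 && anyNA(out)) {
    # measured positions (e.g. tracked centroids) may fall just outside a
    # region; snap them onto the nearest structure within `snap` um
    g <- geometry
    na <- which(is.na(out))
    w2 <- g$channel_width / 2
    hh <- g$loading_half_height
    ax <- abs(x[na])
    sg <- ifelse(x[na] >= 0, 1, -1)
    # 1) pull y onto the nearest channel when within reach
    ycn <- g$channel_centers_y[
      pmax(1, pmin(g$n_channels,
                   round(y[na] / g$channel_pitch + (g$n_channels + 1) / 2)))]
    y2 <- ifelse(abs(y[na] - ycn) <= w2 + snap,
                 pmin(pmax(y[na], ycn - w2 + 0.01), ycn + w2 - 0.01),
                 pmin(pmax(y[na], -hh + 0.01), hh - 0.01))
    lim <- g$reservoir_mouth_x + g$reservoir_depth
    x2 <- sg * pmin(ax, lim - 0.01)
    cand <- point_region_strict(g, x2, y2)
    # 2) still outside: position sits in the channel band but off any
    # channel; snap axially to the loading channel or reservoir mouth
    miss <- is.na(cand)
    if (any(miss)) {
      near_load <- miss & ax - g$mouth_x <= snap
      x2[near_load] <- sg[near_load] * (g$mouth_x - 0.01)
      near_res <- miss & !near_load & g$reservoir_mouth_x - ax <= snap
      x2[near_res] <- sg[near_res] * (g$reservoir_mouth_x + 0.01)
      y3 <- pmin(pmax(y[na], -hh + 0.01), hh - 0.01)
      cand[miss] <- point_region_strict(g, x2[miss], y3[miss])
    }
    out[na] <- cand
  }
  if (!allow_outside && anyNA(out))
    stop(sprintf("%d position(s) outside the device (first: x=%.1f, y=%.1f)",
                 sum(is.na(out)), x[which(is.na(out))[1]], y[which(is.na(out))[1]]))
  out
}

point_region_strict <- function(geometry, x, y) {
  g <- geometry
  n <- length(x)
  out <- rep(NA_character_, n)
  ax <- abs(x)
  side <- ifelse(x >= 0, "fmlp", "ltb4")
  hh <- g$loading_half_height
  w2 <- g$channel_width / 2

  in_res <- ax >= g$reservoir_mouth_x &
    ax <= g$reservoir_mouth_x + g$reservoir_depth & abs(y) <= hh
  out[in_res] <- paste0("reservoir_", side[in_res])

  band <- is.na(out) & ax >= g$mouth_x & ax <= g$reservoir_mouth_x
  if (any(band)) {
    u <- ax[band] - g$mouth_x
    # inside a rung column?
    in_col <- rep(FALSE, sum(band))
    for (ur in g$rung_positions) in_col <- in_col | abs(u - ur) <= w2
    # within a gap between adjacent channels?
    yb <- y[band]
    idx <- findInterval(yb, g$channel_centers_y) # channel at/below
    lo_ok <- idx >= 1 & idx < g$n_channels
    in_gap <- rep(FALSE, sum(band))
    in_gap[lo_ok] <- yb[lo_ok] >= g$channel_centers_y[idx[lo_ok]] + w2 &
      yb[lo_ok] <= g$channel_centers_y[idx[lo_ok] + 1] - w2
    maze <- in_col & in_gap
    # inside a channel?
    near <- pmin(abs(yb - g$channel_centers_y[pmax(idx, 1)]),
                 abs(yb - g$channel_centers_y[pmin(idx + 1, g$n_channels)]))
    chan <- !maze & near <= w2
    bi <- which(band)
    out[bi[maze]] <- paste0("maze_", side[band][maze])
    out[bi[chan]] <- paste0("channel_", side[band][chan])
  }

  in_load <- is.na(out) & ax <= g$mouth_x & abs(y) <= hh
  out[in_load] <- "loading"
  out
}

#' Chemoattractant specification
#'
#' @param name label, e.g. `"fMLP"`.
#' @param molecular_weight molecular weight in daltons.
#' @param reservoir_concentration concentration loaded into the reservoir (nM).
#' @param diffusion_coefficient diffusion coefficient in um^2/s; when `NULL`
#'   it is estimated from the molecular weight by the Stokes-Einstein
#'   relation (see [estimate_diffusion_coefficient()]).
#' @param temperature,viscosity,radius_coefficient passed to
#'   [estimate_diffusion_coefficient()] when `diffusion_coefficient` is `NULL`.
#' @return An object of class `muc3_attractant`.
#' @examples
#' chemoattractant_spec("fMLP", 438, 10)
#' @export
chemoattractant_spec <- function(name, molecular_weight, reservoir_concentration,
                                 diffusion_coefficient = NULL,
                                 temperature = 310, viscosity = 6.913e-4,
                                 radius_coefficient = 0.066) {
  stopifnot(molecular_weight > 0, reservoir_concentration >= 0)
  if (is.null(diffusion_coefficient))
    diffusion_coefficient <- estimate_diffusion_coefficient(
      molecular_weight, temperature, viscosity, radius_coefficient)
  stopifnot(diffusion_coefficient > 0)
  structure(list(name = name,
                 molecular_weight = molecular_weight,
                 reservoir_concentration = reservoir_concentration,
                 diffusion_coefficient = diffusion_coefficient),
            class = "muc3_attractant")
}

#' @export
print.muc3_attractant <- function(x, ...) {
  cat(sprintf("<muc3_attractant> %s: MW %g Da, reservoir %g nM, D %.1f um^2/s\n",
              x$name, x$molecular_weight, x$reservoir_concentration,
              x$diffusion_coefficient))
  invisible(x)
}

#' Default chemoattractant pair used in the assay
#'
#' fMLP at 10 nM (MW 438 Da) on the +x side and LTB4 at 100 nM (MW 336 Da)
#' on the -x side.
#'
#' @return Named list of two [chemoattractant_spec()] objects.
#' @export
default_attractants <- function() {
  list(fmlp = chemoattractant_spec("fMLP", 438, 10),
       ltb4 = chemoattractant_spec("LTB4", 336, 100))
}
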