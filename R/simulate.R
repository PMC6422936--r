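#' Simulate a migration experiment in the chip
#'
#' Agent-based biased persistent random walk in the device geometry.  Cells
#' start uniformly distributed in the central loading channel.  At every
#' 2.5-min step (the imaging interval) a motile loading-channel cell may
#' commit to a migration channel with a per-side hazard proportional to
#' `1 + bias * S`, where `S` is that side's normalized gradient steepness
#' taken from the solved field (S = 0 without chemoattractant, so entry then
#' falls back to the gradient-free baseline hazard); it then walks to the
#' mouth of the nearest channel on that side at its migration speed before
#' entering, so consecutive positions always stay within one step.  Inside a
#' channel the
#' cell advances toward the reservoir with a per-cell speed drawn from the
#' preset's side-specific distribution; with probability `reversal_prob` per
#' step it flips and retreats (realigning up-gradient with fixed
#' probability per subsequent step).  When it crosses a maze junction it
#' branches into the rung with probability `maze_entry_weight / attenuation`
#' and performs an unbiased walk along the rung until it re-joins a channel.
#' Cells that reach a reservoir are absorbed; cells that retreat past the
#' mouth rejoin the loading channel and may re-enter later.
#'
#' The run is fully reproducible: identical `(preset, seed)` (and identical
#' remaining arguments) give bit-identical tracks.
#'
#' @param preset a [priming_preset()].
#' @param geometry a [device_geometry()].
#' @param fields named list of `muc3_field`s (`fmlp`, `ltb4`) for the
#'   dual-gradient condition, or `NULL` for no chemoattractant.
#' @param condition `"dual_gradient"` or `"no_chemoattractant"`; defaults to
#'   the former when `fields` is supplied.
#' @param n_cells number of cells loaded (>= 1).
#' @param duration experiment duration (min).
#' @param dt frame interval (min).
#' @param seed integer seed for this run.
#' @param min_separation minimum centre-to-centre distance (um) between
#'   seeded cells in the loading channel (nuclear exclusion); enforced by
#'   rejection sampling with a bounded number of attempts, so very dense
#'   loadings may retain closer pairs.
#' @return An object of class `muc3_run`: the run configuration plus
#'   `tracks`, a `data.frame` with columns `cell_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`, `region`.
#' @examples
#' run <- simulate_experiment(lps_presets()$unstimulated,
#'                            fields = default_fields(t_end = 30),
#'                            n_cells = 50, duration = 30, seed = 1)
#' summary(run)
#' @export
simulate_experiment <- function(preset, geometry = device_geometry(),
                                fields = NULL, condition = NULL,
                                n_cells = 500, duration = 300, dt = 2.5,
                                seed = 1, min_separation = 12) {
  stopifnot(inherits(preset, "muc3_preset"))
  if (is.null(condition))
    condition <- if (is.null(fields)) "no_chemoattractant" else "dual_gradient"
  condition <- match.arg(condition, c("dual_gradient", "no_chemoattractant"))
  if (condition == "dual_gradient" && is.null(fields))
    stop("dual_gradient condition requires gradient fields (see default_fields())")
  if (n_cells < 1) stop("n_cells must be >= 1")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) stop("dt must divide duration")
  n_steps <- as.integer(round(n_steps))
  g <- geometry
  k <- .muc3

  # normalized gradient steepness per side at each step time:
  # |OLS slope of c/c0| * L, ~1 once the linear gradient has formed.
  tt <- seq_len(n_steps) * dt
  if (condition == "dual_gradient") {
    steep <- function(f) {
      s <- vapply(pmin(tt, max(f$t_min)), function(t)
        abs(gradient_slope(f, t)), numeric(1))
      s * f$channel_length / f$spec$reservoir_concentration
    }
    S_f <- steep(fields$fmlp); S_l <- steep(fields$ltb4)
  } else {
    S_f <- S_l <- rep(0, n_steps)
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  n <- n_cells
  hh <- g$loading_half_height
  w2 <- g$channel_width / 2
  yc <- g$channel_centers_y
  L <- g$channel_length
  rungs <- g$rung_positions
  p_maze <- min(0.95, preset$maze_entry_weight / g$maze_attenuation)

  motile_p <- if (condition == "dual_gradient") preset$motile_fraction else
    preset$spontaneous_fraction
  motile <- stats::runif(n) < motile_p
  # per-cell base speeds per side (truncated at the model floor)
  sbase <- cbind(
    pmax(k$min_speed, stats::rnorm(n, preset$speed_mean_fmlp, preset$speed_sd_fmlp)),
    pmax(k$min_speed, stats::rnorm(n, preset$speed_mean_ltb4, preset$speed_sd_ltb4)))

  # state: 1 loading, 2 channel, 3 maze, 4 reservoir
  state <- rep(1L, n)
  side <- rep(0L, n)       # 0 none, 1 fmlp, 2 ltb4
  chan <- rep(0L, n)       # channel index 1..n_channels
  gap <- rep(0L, n)        # maze gap index (between chan gap and gap+1)
  u <- rep(0, n)           # axial distance from the mouth (0..L)
  dirn <- rep(1L, n)       # +1 toward reservoir (channel) / +y (maze)
  x <- stats::runif(n, -g$mouth_x + 1, g$mouth_x - 1)
  y <- stats::runif(n, -hh + 1, hh - 1)
  if (min_separation > 0 && n > 1) {
    # nuclear exclusion at seeding: resample cells closer than
    # min_separation to an already-placed cell (bounded attempts)
    for (i in 2:n) {
      for (att in seq_len(30)) {
        d2 <- (x[seq_len(i - 1)] - x[i])^2 + (y[seq_len(i - 1)] - y[i])^2
        if (min(d2) >= min_separation^2) break
        x[i] <- stats::runif(1, -g$mouth_x + 1, g$mouth_x - 1)
        y[i] <- stats::runif(1, -hh + 1, hh - 1)
      }
    }
  }

  nf <- n_steps + 1L
  X <- matrix(NA_real_, n, nf); Y <- matrix(NA_real_, n, nf)
  REG <- matrix(NA_integer_, n, nf)
  # state 5 = committed but still walking inside the loading channel
  reg_code <- function() {
    code <- integer(n)
    code[state == 1L | state == 5L] <- 1L
    code[state == 2L] <- 1L + side[state == 2L]
    code[state == 3L] <- 3L + side[state == 3L]
    code[state == 4L] <- 5L + side[state == 4L]
    code
  }
  X[, 1] <- x; Y[, 1] <- y; REG[, 1] <- reg_code()

  sgn <- function(s) ifelse(s == 1L, 1, -1)

  for (step in seq_len(n_steps)) {
    u_prev <- u          # axial order at the start of the step (queueing)
    u_prev[state != 2L] <- -1
    ## -- loading-channel cells ------------------------------------------
    il <- which(state == 1L)
    if (length(il)) {
      im <- il[motile[il]]
      ist <- il[!motile[il]]
      if (length(ist)) {
        x[ist] <- pmin(pmax(x[ist] + stats::rnorm(length(ist), 0, k$static_jitter),
                            -g$mouth_x + 0.5), g$mouth_x - 0.5)
        y[ist] <- pmin(pmax(y[ist] + stats::rnorm(length(ist), 0, k$static_jitter),
                            -hh + 0.5), hh - 0.5)
      }
      if (length(im)) {
        hf <- k$entry_hazard * (1 + preset$bias_fmlp * S_f[step])
        hl <- k$entry_hazard * (1 + preset$bias_ltb4 * S_l[step])
        p_tot <- 1 - exp(-(hf + hl) * dt)
        ent <- im[stats::runif(length(im)) < p_tot]
        rest <- setdiff(im, ent)
        if (length(rest)) {
          x[rest] <- pmin(pmax(x[rest] + stats::rnorm(length(rest), 0, k$loading_jitter),
                               -g$mouth_x + 0.5), g$mouth_x - 0.5)
          y[rest] <- pmin(pmax(y[rest] + stats::rnorm(length(rest), 0, k$loading_jitter),
                               -hh + 0.5), hh - 0.5)
        }
        if (length(ent)) {
          # commit to the nearest channel on the chosen side and walk to
          # its mouth (no teleporting: steps stay within speed * dt)
          sd_f <- stats::runif(length(ent)) < hf / (hf + hl)
          side[ent] <- ifelse(sd_f, 1L, 2L)
          chan[ent] <- pmax(1L, pmin(g$n_channels,
            as.integer(round(y[ent] / g$channel_pitch + (g$n_channels + 1) / 2))))
          state[ent] <- 5L
        }
      }
    }

    ## -- committed cells walking to their channel mouth --------------------
    # snapshot the channel roster first: cells entering a channel this step
    # must not also take a channel move this step
    ic <- which(state == 2L)
    iw <- which(state == 5L)
    if (length(iw)) {
      sp <- pmax(k$min_speed,
                 sbase[cbind(iw, side[iw])] +
                   stats::rnorm(length(iw), 0, k$step_speed_sd))
      tx <- sgn(side[iw]) * g$mouth_x
      ty <- yc[chan[iw]]
      ddx <- tx - x[iw]; ddy <- ty - y[iw]
      dist <- sqrt(ddx^2 + ddy^2)
      reach <- dist <= sp * dt
      # a 10-um mouth admits one cell at a time: entry is blocked while
      # another cell occupies the first stretch of the channel
      if (any(reach)) {
        for (i in iw[reach]) {
          occupied <- any(state == 2L & side == side[i] & chan == chan[i] &
                            u < min_separation)
          if (occupied) {
            reach[iw == i] <- FALSE   # wait at the mouth this frame
          } else {
            state[i] <- 2L
            u[i] <- 0.05
            dirn[i] <- 1L
            x[i] <- sgn(side[i]) * (g$mouth_x + 0.05)
            y[i] <- yc[chan[i]] + stats::runif(1, -w2 + 1, w2 - 1)
          }
        }
      }
      imv <- iw[!reach & state[iw] == 5L]
      blocked <- !reach & state[iw] == 5L
      if (length(imv)) {
        # blocked walkers hold their position; the rest keep walking
        hold <- dist[blocked] <= sp[blocked] * dt
        frac <- ifelse(hold, 0, (sp * dt / dist)[blocked])
        x[imv] <- x[imv] + ddx[blocked] * frac
        y[imv] <- y[imv] + ddy[blocked] * frac
        x[imv] <- pmin(pmax(x[imv], -g$mouth_x + 0.2), g$mouth_x - 0.2)
      }
    }

    ## -- channel cells (roster snapshotted before this step's entries) ----
    if (length(ic)) {
      sp <- pmax(k$min_speed,
                 sbase[cbind(ic, side[ic])] +
                   stats::rnorm(length(ic), 0, k$step_speed_sd))
      fwd <- dirn[ic] == 1L
      flip <- stats::runif(length(ic)) <
        ifelse(fwd, preset$reversal_prob, k$realign_prob)
      dirn[ic][flip] <- -dirn[ic][flip]
      du <- ifelse(dirn[ic] == 1L, 1, -1) * sp * dt
      u_new <- u[ic] + du

      # first maze junction crossed this step (if any)
      cross_u <- rep(NA_real_, length(ic))
      for (ur in rungs) {
        hit <- (u[ic] < ur & u_new > ur) | (u[ic] > ur & u_new < ur)
        take <- hit & (is.na(cross_u) |
                         abs(ur - u[ic]) < abs(cross_u - u[ic]))
        cross_u[take] <- ur
      }
      can_branch <- !is.na(cross_u)
      branch <- can_branch & stats::runif(length(ic)) < p_maze
      # a rung must exist on the chosen vertical side
      up <- stats::runif(length(ic)) < 0.5
      ci <- chan[ic]
      up[branch & ci == g$n_channels] <- FALSE
      up[branch & ci == 1L] <- TRUE

      ib <- ic[branch]
      if (length(ib)) {
        state[ib] <- 3L
        gap[ib] <- chan[ib] - 1L + up[branch]
        u[ib] <- cross_u[branch]
        x[ib] <- sgn(side[ib]) * (g$mouth_x + u[ib])
        y[ib] <- yc[chan[ib]] + ifelse(up[branch], w2 + 0.5, -w2 - 0.5)
        dirn[ib] <- ifelse(up[branch], 1L, -1L)
      }
      io <- ic[!branch]
      if (length(io)) {
        un <- u_new[!branch]
        absorbed <- un >= L
        back <- !absorbed & un <= 0
        stay <- !absorbed & !back
        ia <- io[absorbed]
        if (length(ia)) {
          state[ia] <- 4L
          over <- pmin(un[absorbed] - L, g$reservoir_depth - 15)
          x[ia] <- sgn(side[ia]) * (g$reservoir_mouth_x + 5 + pmax(over, 0))
          y[ia] <- pmin(pmax(y[ia] + stats::runif(length(ia), -12, 12),
                             -hh + 2), hh - 2)
        }
        ibk <- io[back]
        if (length(ibk)) {
          state[ibk] <- 1L
          side[ibk] <- 0L
          x[ibk] <- sgn_back <- sign(x[ibk]) * (g$mouth_x - stats::runif(length(ibk), 1, 4))
        }
        isy <- io[stay]
        if (length(isy)) {
          u[isy] <- un[stay]
          x[isy] <- sgn(side[isy]) * (g$mouth_x + u[isy])
          y[isy] <- pmin(pmax(y[isy] + stats::rnorm(length(isy), 0, k$channel_jitter),
                              yc[chan[isy]] - w2 + 0.5), yc[chan[isy]] + w2 - 0.5)
        }
      }
    }

    ## -- maze cells -------------------------------------------------------
    iz <- which(state == 3L)
    if (length(iz)) {
      sp <- pmax(k$min_speed,
                 sbase[cbind(iz, side[iz])] +
                   stats::rnorm(length(iz), 0, k$step_speed_sd))
      flip <- stats::runif(length(iz)) < k$maze_flip_prob
      dirn[iz][flip] <- -dirn[iz][flip]
      y_new <- y[iz] + ifelse(dirn[iz] == 1L, 1, -1) * sp * dt
      y_lo <- yc[gap[iz]] + w2
      y_hi <- yc[gap[iz] + 1L] - w2
      exit_up <- y_new >= y_hi
      exit_dn <- !exit_up & y_new <= y_lo
      stay <- !exit_up & !exit_dn
      ie <- iz[exit_up | exit_dn]
      if (length(ie)) {
        chan[ie] <- gap[ie] + (exit_up[exit_up | exit_dn])
        state[ie] <- 2L
        y[ie] <- yc[chan[ie]] + stats::runif(length(ie), -w2 + 1, w2 - 1)
        x[ie] <- sgn(side[ie]) * (g$mouth_x + u[ie])
        dirn[ie] <- ifelse(stats::runif(length(ie)) < k$exit_align_prob, 1L, -1L)
      }
      isy <- iz[stay]
      if (length(isy)) {
        y[isy] <- y_new[stay]
        x[isy] <- sgn(side[isy]) *
          pmin(pmax(abs(x[isy]) + stats::rnorm(length(isy), 0, k$static_jitter),
                    g$mouth_x + u[isy] - w2 + 0.5),
               g$mouth_x + u[isy] + w2 - 0.5)
      }
    }

    ## -- reservoir cells (absorbed; residual jitter only) -----------------
    ir <- which(state == 4L)
    if (length(ir)) {
      x[ir] <- sgn(side[ir]) *
        pmin(pmax(abs(x[ir]) + stats::rnorm(length(ir), 0, k$reservoir_jitter),
                  g$reservoir_mouth_x + 2),
             g$reservoir_mouth_x + g$reservoir_depth - 2)
      y[ir] <- pmin(pmax(y[ir] + stats::rnorm(length(ir), 0, k$reservoir_jitter),
                         -hh + 0.5), hh - 0.5)
    }

    ## -- single-file queueing inside migration channels --------------------
    # a 10-um channel holds cells in single file: cells can neither overtake
    # nor pass through one another, so enforce an axial minimum spacing per
    # channel while preserving the order cells held at the start of the step
    if (min_separation > 0) {
      icq <- which(state == 2L)
      if (length(icq) > 1) {
        key <- paste(side[icq], chan[icq])
        for (grp in split(icq, key)) {
          if (length(grp) < 2) next
          # rank by last frame's position; newcomers (channel entrants and
          # maze returners) slot in at their current position
          rank_u <- ifelse(u_prev[grp] >= 0, u_prev[grp], u[grp])
          ord <- grp[order(-rank_u, -u[grp])]
          for (ii in 2:length(ord)) {
            lead <- u[ord[ii - 1]]
            if (u[ord[ii]] > lead - min_separation)
              u[ord[ii]] <- max(lead - min_separation, 0.05)
          }
          x[ord] <- sgn(side[ord]) * (g$mouth_x + u[ord])
        }
      }
    }

    ## -- soft nuclear exclusion in the 2-D compartments -------------------
    # cells in the loading channel and reservoirs cannot overlap; push
    # pairs closer than min_separation apart (single relaxation pass)
    if (min_separation > 0) {
      for (grp in list(which(state == 1L | state == 5L),
                       which(state == 4L & side == 1L),
                       which(state == 4L & side == 2L))) {
        if (length(grp) < 2) next
        xi <- x[grp]; yi <- y[grp]
        dx <- outer(xi, xi, "-"); dy <- outer(yi, yi, "-")
        d <- sqrt(dx^2 + dy^2)
        diag(d) <- Inf
        close_ij <- which(d < min_separation & upper.tri(d), arr.ind = TRUE)
        if (nrow(close_ij)) {
          for (rr in seq_len(nrow(close_ij))) {
            i <- close_ij[rr, 1]; j <- close_ij[rr, 2]
            dd <- max(d[i, j], 0.5)
            # relax gently: at most 2.5 um per cell per frame
            push <- min((min_separation - dd) / 2, 2.5)
            ux <- dx[j, i] / dd; uy <- dy[j, i] / dd
            xi[j] <- xi[j] + ux * push; yi[j] <- yi[j] + uy * push
            xi[i] <- xi[i] - ux * push; yi[i] <- yi[i] - uy * push
          }
          if (state[grp[1]] != 4L) {
            xi <- pmin(pmax(xi, -g$mouth_x + 0.5), g$mouth_x - 0.5)
          } else {
            xi <- sign(xi) * pmin(pmax(abs(xi), g$reservoir_mouth_x + 2),
                                  g$reservoir_mouth_x + g$reservoir_depth - 2)
          }
          yi <- pmin(pmax(yi, -hh + 0.5), hh - 0.5)
          x[grp] <- xi; y[grp] <- yi
        }
      }
    }

    X[, step + 1L] <- x; Y[, step + 1L] <- y; REG[, step + 1L] <- reg_code()
  }

  tracks <- data.frame(
    cell_id = rep(seq_len(n), each = nf),
    frame = rep(seq_len(nf), times = n),
    t_min = rep((seq_len(nf) - 1L) * dt, times = n),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y)),
    region = muc3_regions[as.vector(t(REG))],
    stringsAsFactors = FALSE)

  structure(list(preset = preset, geometry = g, condition = condition,
                 n_cells = n, duration = duration, dt = dt, seed = seed,
                 preset_hash = preset_hash(preset), tracks = tracks),
            class = "muc3_run")
}

#' Build the default gradient fields for the dual-gradient condition
#'
#' Solves channel diffusion for the default chemoattractant pair (fMLP 10 nM
#' on +x, LTB4 100 nM on -x) under the sink boundary.
#'
#' @param geometry a [device_geometry()].
#' @param t_end solved duration (min); use at least the experiment duration.
#' @param ... further arguments to [solve_channel_diffusion()].
#' @return Named list of two `muc3_field`s (`fmlp`, `ltb4`).
#' @export
default_fields <- function(geometry = device_geometry(), t_end = 300, ...) {
  att <- default_attractants()
  list(fmlp = solve_channel_diffusion(att$fmlp, geometry, t_end = t_end, ...),
       ltb4 = solve_channel_diffusion(att$ltb4, geometry, t_end = t_end, ...))
}

#' @export
print.muc3_run <- function(x, ...) {
  cat(sprintf("<muc3_run> preset %s (hash %s), %s, %d cells, %g min @ %g-min frames, seed %d\n",
              x$preset$label, x$preset_hash, x$condition, x$n_cells,
              x$duration, x$dt, x$seed))
  final <- x$tracks[x$tracks$frame == max(x$tracks$frame), ]
  print(table(factor(final$region, levels = muc3_regions)))
  invisible(x)
}

#' @export
summary.muc3_run <- function(object, ...) migration_metrics(object, ...)
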