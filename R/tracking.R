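#' Detect spots in one frame
#'
#' Difference-of-Gaussians blob detection (a standard approximation to the
#' Laplacian of Gaussian) at scale `sigma`, followed by 8-neighbourhood
#' local-maximum selection and sub-pixel refinement by a 1-D quadratic fit
#' along each axis.  Spots whose DoG response falls below `threshold` are
#' discarded; with `threshold = NULL` a robust automatic cut of
#' `median + 8 * mad` of the response image is used.
#'
#' @param frame numeric image matrix (rows = y, columns = x).
#' @param sigma detection scale (px); match to the spot sd.
#' @param threshold minimum DoG response (a.u.), or `NULL` for automatic.
#' @param pixel_size um per px, for reporting positions in um.
#' @param origin um coordinates of the outer corner of pixel (1, 1),
#'   `c(x0, y0)`.
#' @return `data.frame` with `x_um`, `y_um`, `intensity` (DoG response).
#' @export
detect_spots <- function(frame, sigma = 1.25, threshold = NULL,
                         pixel_size = 1, origin = c(0, 0)) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  if (sigma <= 0) stop("sigma must be positive")
  g1 <- EBImage::imageData(EBImage::gblur(frame, sigma = sigma))
  g2 <- EBImage::imageData(EBImage::gblur(frame, sigma = 1.6 * sigma))
  dog <- g1 - g2
  if (is.null(threshold))
    threshold <- stats::median(dog) + 8 * stats::mad(dog)

  nr <- nrow(dog); nc <- ncol(dog)
  core <- dog[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- dog[2:(nr - 1) + dy, 2:(nc - 1) + dx]
    # strict inequality toward later neighbours breaks plateau ties so a
    # peak straddling two pixels yields exactly one maximum
    is_max <- is_max & if (dy > 0 || (dy == 0 && dx > 0)) core > nb else core >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0)))
  ry <- idx[, 1] + 1L; cx <- idx[, 2] + 1L

  # sub-pixel refinement: vertex of the parabola through the 3 samples
  refine <- function(fm1, f0, fp1) {
    den <- fm1 - 2 * f0 + fp1
    d <- ifelse(abs(den) > 1e-12, 0.5 * (fm1 - fp1) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dyv <- refine(dog[cbind(ry - 1L, cx)], dog[cbind(ry, cx)], dog[cbind(ry + 1L, cx)])
  dxv <- refine(dog[cbind(ry, cx - 1L)], dog[cbind(ry, cx)], dog[cbind(ry, cx + 1L)])

  data.frame(
    x_um = origin[1] + (cx + dxv - 0.5) * pixel_size,
    y_um = origin[2] + (ry + dyv - 0.5) * pixel_size,
    intensity = dog[cbind(ry, cx)])
}

#' Link detected spots into tracks
#'
#' Frame-to-frame assignment between open tracks and new spots.  The default
#' greedy linker sorts all candidate pairs by distance and accepts them in
#' order; the `"optimal"` mode minimises the total displacement over all
#' assignments by exhaustive enumeration (intended for small validation
#' scenarios).  Candidate distances are measured to a constant-velocity
#' prediction of each track's next position (`motion = "linear"`, apt for
#' cells migrating persistently up a channel); `motion = "brownian"` uses
#' the last seen position instead.  Links longer than `max_displacement`
#' per elapsed frame are forbidden; tracks missing from up to `max_gap`
#' consecutive frames are bridged.
#'
#' @param spot_sets list of per-frame spot tables (see [detect_spots()]),
#'   ordered by frame.
#' @param max_displacement maximum link length per elapsed frame (um).
#' @param max_gap maximum number of bridged missing frames.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @param motion `"linear"` (default) or `"brownian"` candidate prediction.
#' @param dt frame interval (min), used to fill the `t_min` column.
#' @return Track `data.frame` with `cell_id`, `frame`, `t_min`, `x_um`,
#'   `y_um` (the shared track schema; regions can be added with
#'   [assign_regions()]).
#' @export
link_spots <- function(spot_sets, max_displacement = 50, max_gap = 2,
                       method = c("greedy", "optimal"),
                       motion = c("linear", "brownian"), dt = 2.5) {
  method <- match.arg(method)
  motion <- match.arg(motion)
  if (!length(spot_sets)) stop("no spot sets supplied")
  # open track state; vx/vy hold an exponentially smoothed velocity so the
  # prediction follows persistent motion without amplifying jitter
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  vx <- numeric(0); vy <- numeric(0)
  track_id <- integer(0)
  next_id <- 1L
  ema <- 0.6
  rows <- vector("list", length(spot_sets))

  for (f in seq_along(spot_sets)) {
    sp <- spot_sets[[f]]
    n_new <- nrow(sp)
    assigned_track <- rep(NA_integer_, n_new)
    open <- which(f - last_f <= max_gap + 1L)
    if (length(open) && n_new) {
      gap_n <- f - last_f[open]
      if (motion == "linear") {
        px <- last_x[open] + gap_n * vx[open]
        py <- last_y[open] + gap_n * vy[open]
      } else {
        px <- last_x[open]; py <- last_y[open]
      }
      dx <- outer(px, sp$x_um, "-")
      dy <- outer(py, sp$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      # feasibility stays anchored to the last *seen* position
      dist0 <- sqrt(outer(last_x[open], sp$x_um, "-")^2 +
                      outer(last_y[open], sp$y_um, "-")^2)
      feas <- dist0 <= max_displacement * gap_n
      if (method == "greedy") {
        used_o <- logical(length(open)); used_n <- logical(n_new)
        # pass 1: lock unambiguous short-range pairs (mutually nearest by
        # last seen position) so a mispredicted track cannot steal the spot
        # of a well-tracked neighbour
        lock_radius <- 6
        near_o <- apply(dist0, 1, which.min)
        near_n <- apply(dist0, 2, which.min)
        for (i in seq_along(open)) {
          j <- near_o[i]
          if (near_n[j] == i && dist0[i, j] <= lock_radius && feas[i, j] &&
              !used_o[i] && !used_n[j]) {
            used_o[i] <- TRUE; used_n[j] <- TRUE
            assigned_track[j] <- open[i]
          }
        }
        # pass 2: within each connected component of the remaining
        # feasibility graph, pick the assignment minimising total
        # prediction distance plus a miss penalty per unmatched spot or
        # freshly seen track (exhaustive for small components, greedy for
        # large ones)
        rem_o <- which(!used_o); rem_n <- which(!used_n)
        if (length(rem_o) && length(rem_n)) {
          fresh <- last_f[open[rem_o]] == f - 1L
          comp <- link_components(feas[rem_o, rem_n, drop = FALSE])
          for (cc in comp) {
            oi <- rem_o[cc$o]; nj <- rem_n[cc$n]
            sub_d <- dist[oi, nj, drop = FALSE]
            sub_f <- feas[oi, nj, drop = FALSE]
            if (length(cc$o) + length(cc$n) <= 8) {
              a <- best_assignment(sub_d, sub_f, fresh[cc$o],
                                   miss = max_displacement)
            } else {
              a <- rep(NA_integer_, length(nj))
              ordc <- order(sub_d)
              uo <- logical(length(oi)); un <- logical(length(nj))
              for (kk in ordc) {
                if (!sub_f[kk]) next
                i <- (kk - 1L) %% length(oi) + 1L
                j <- (kk - 1L) %/% length(oi) + 1L
                if (uo[i] || un[j]) next
                uo[i] <- TRUE; un[j] <- TRUE; a[j] <- i
              }
            }
            for (j in seq_along(nj)) if (!is.na(a[j])) {
              used_o[oi[a[j]]] <- TRUE; used_n[nj[j]] <- TRUE
              assigned_track[nj[j]] <- open[oi[a[j]]]
            }
          }
        }
      } else {
        assigned_track <- assign_optimal(dist, feas, open)
      }
    }
    # update matched tracks, start new ones
    for (j in seq_len(n_new)) {
      ti <- assigned_track[j]
      if (is.na(ti)) {
        ti <- length(track_id) + 1L
        track_id[ti] <- next_id
        next_id <- next_id + 1L
        last_x[ti] <- sp$x_um[j]; last_y[ti] <- sp$y_um[j]; last_f[ti] <- 0L
        vx[ti] <- 0; vy[ti] <- 0
        assigned_track[j] <- ti
      } else {
        gp <- f - last_f[ti]
        vx[ti] <- (1 - ema) * vx[ti] + ema * (sp$x_um[j] - last_x[ti]) / gp
        vy[ti] <- (1 - ema) * vy[ti] + ema * (sp$y_um[j] - last_y[ti]) / gp
      }
      last_x[ti] <- sp$x_um[j]; last_y[ti] <- sp$y_um[j]; last_f[ti] <- f
    }
    if (n_new)
      rows[[f]] <- data.frame(cell_id = track_id[assigned_track],
                              frame = f, t_min = (f - 1) * dt,
                              x_um = sp$x_um, y_um = sp$y_um)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), frame = integer(0),
                      t_min = numeric(0), x_um = numeric(0), y_um = numeric(0))
  out <- out[order(out$cell_id, out$frame), ]
  rownames(out) <- NULL
  out
}

## Connected components of a bipartite feasibility matrix (tracks x spots).
## Returns a list of components, each with track indices $o and spot
## indices $n (singleton spots/tracks with no feasible partner included).
link_components <- function(feas) {
  n_o <- nrow(feas); n_n <- ncol(feas)
  comp_o <- rep(0L, n_o); comp_n <- rep(0L, n_n)
  cid <- 0L
  for (s in seq_len(n_o)) {
    if (comp_o[s]) next
    cid <- cid + 1L
    qo <- s
    while (length(qo)) {
      i <- qo[1]; qo <- qo[-1]
      if (comp_o[i]) next
      comp_o[i] <- cid
      js <- which(feas[i, ] & comp_n == 0L)
      comp_n[js] <- cid
      for (j in js) qo <- c(qo, which(feas[, j] & comp_o == 0L))
    }
  }
  out <- lapply(seq_len(cid), function(k)
    list(o = which(comp_o == k), n = which(comp_n == k)))
  orphan <- which(comp_n == 0L)
  if (length(orphan))
    out <- c(out, lapply(orphan, function(j) list(o = integer(0), n = j)))
  out[vapply(out, function(cc) length(cc$n) > 0, logical(1))]
}

## Exhaustive assignment of spots to tracks minimising total distance plus
## `miss` for every unmatched spot and every unmatched freshly-seen track.
best_assignment <- function(dist, feas, fresh, miss) {
  n_o <- nrow(dist); n_n <- ncol(dist)
  if (n_o == 0) return(rep(NA_integer_, n_n))
  choices <- c(NA_integer_, seq_len(n_o))
  grid <- do.call(expand.grid, rep(list(choices), n_n))
  best <- rep(NA_integer_, n_n); best_cost <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[!is.na(a)]
    if (anyDuplicated(used)) next
    ok <- !is.na(a)
    if (any(ok & !feas[cbind(a, seq_len(n_n))])) next
    cost <- sum(dist[cbind(a[ok], which(ok))]) +
      miss * sum(!ok) + miss * sum(fresh & !(seq_len(n_o) %in% used))
    if (cost < best_cost) { best_cost <- cost; best <- a }
  }
  best
}

## Exhaustive minimum-total-distance assignment (small problems only).
assign_optimal <- function(dist, feas, open) {
  n_o <- nrow(dist); n_n <- ncol(dist)
  if (n_o > 9 || n_n > 9)
    stop("optimal assignment is exhaustive and limited to <= 9 spots; ",
         "use method = 'greedy' for dense fields")
  dist[!feas] <- NA
  best <- NULL; best_cost <- Inf
  # choose, for each new spot, an open track or none
  choices <- c(NA_integer_, seq_len(n_o))
  grid <- do.call(expand.grid, rep(list(choices), n_n))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    used <- a[!is.na(a)]
    if (anyDuplicated(used)) next
    d <- dist[cbind(a, seq_len(n_n))]
    if (any(is.na(d) & !is.na(a))) next
    cost <- sum(d, na.rm = TRUE) + 1e6 * sum(is.na(a)) # prefer linking
    if (cost < best_cost) { best_cost <- cost; best <- a }
  }
  out <- rep(NA_integer_, n_n)
  ok <- !is.na(best)
  out[ok] <- open[best[ok]]
  out
}

#' Track a rendered stack end to end
#'
#' Runs [detect_spots()] on every frame and [link_spots()] over the results,
#' using the stack's pixel metadata, and returns tracks in the shared
#' schema.  Defaults follow the rendered point-spread function and the
#' observed single-cell velocity range (up to ~20 um/min, i.e. 50 um per
#' 2.5-min frame).
#'
#' @param stack a `muc3_stack` (or list of matrices, with `pixel_size`,
#'   `origin` and `dt` given explicitly).
#' @param sigma,threshold passed to [detect_spots()].
#' @param max_displacement,max_gap,method,motion passed to [link_spots()].
#' @param geometry optional [device_geometry()]; when given, regions are
#'   assigned to the output.
#' @param pixel_size,origin,dt metadata overrides for plain lists.
#' @return Track `data.frame`.
#' @export
track_stack <- function(stack, sigma = NULL, threshold = NULL,
                        max_displacement = 50, max_gap = 2,
                        method = "greedy", motion = "linear", geometry = NULL,
                        pixel_size = NULL, origin = NULL, dt = NULL) {
  if (inherits(stack, "muc3_stack")) {
    frames <- stack$frames
    pixel_size <- pixel_size %||% stack$pixel_size
    origin <- origin %||% stack$origin
    dt <- dt %||% stack$dt
    sigma <- sigma %||% stack$psf_sigma
  } else {
    frames <- stack
    if (is.null(pixel_size) || is.null(origin) || is.null(dt))
      stop("pixel_size, origin and dt are required for plain frame lists")
    sigma <- sigma %||% 1.25
  }
  spot_sets <- lapply(frames, detect_spots, sigma = sigma,
                      threshold = threshold, pixel_size = pixel_size,
                      origin = origin)
  tracks <- link_spots(spot_sets, max_displacement = max_displacement,
                       max_gap = max_gap, method = method, motion = motion,
                       dt = dt)
  if (!is.null(geometry) && nrow(tracks))
    tracks <- assign_regions(tracks, geometry, snap = 2 * pixel_size)
  tracks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare recovered tracks against ground truth
#'
#' Matches detections to ground-truth positions frame by frame (nearest
#' neighbour within `dist_tol`) to give spot-level recall/precision and the
#' mean localisation error, and counts a ground-truth track as *recovered*
#' when a single recovered track identity matches it on at least
#' `min_overlap` of its frames.
#'
#' @param truth ground-truth track table.
#' @param found recovered track table.
#' @param dist_tol matching radius (um).
#' @param min_overlap fraction of frames a single identity must cover.
#' @return List with `recall`, `precision`, `mean_loc_error_um`,
#'   `track_recovery`.
#' @export
evaluate_tracking <- function(truth, found, dist_tol = 6, min_overlap = 0.8) {
  frames <- sort(unique(truth$frame))
  tp <- 0L; fn <- 0L; fp <- 0L
  err <- numeric(0)
  # per truth cell, tally which found id matched at each frame
  match_id <- list()
  for (f in frames) {
    tru <- truth[truth$frame == f, ]
    det <- found[found$frame == f, ]
    if (!nrow(det)) { fn <- fn + nrow(tru); next }
    dx <- outer(tru$x_um, det$x_um, "-")
    dy <- outer(tru$y_um, det$y_um, "-")
    dist <- sqrt(dx^2 + dy^2)
    used <- logical(nrow(det))
    for (i in order(apply(dist, 1, min))) {
      j <- which.min(replace(dist[i, ], used, Inf))
      if (is.finite(dist[i, j]) && dist[i, j] <= dist_tol && !used[j]) {
        used[j] <- TRUE; tp <- tp + 1L
        err <- c(err, dist[i, j])
        key <- as.character(tru$cell_id[i])
        match_id[[key]] <- c(match_id[[key]], det$cell_id[j])
      } else fn <- fn + 1L
    }
    fp <- fp + sum(!used)
  }
  n_frames_per <- table(truth$cell_id)
  recovered <- vapply(names(n_frames_per), function(k) {
    m <- match_id[[k]]
    if (is.null(m)) return(FALSE)
    max(table(m)) >= min_overlap * n_frames_per[[k]]
  }, logical(1))
  list(recall = tp / (tp + fn),
       precision = tp / (tp + fp),
       mean_loc_error_um = mean(err),
       track_recovery = mean(recovered))
}
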