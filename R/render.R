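#' Render synthetic nuclear-stain frames from a run
#'
#' Emulates time-lapse imaging of Hoechst-stained nuclei: each cell becomes
#' an isotropic Gaussian spot at its position, on a constant background,
#' with Poisson shot noise and additive Gaussian read noise.  The run's
#' tracks are attached as the ground-truth table.
#'
#' @param run a `muc3_run`.
#' @param pixel_size image scale (um/px).
#' @param psf_sigma spot standard deviation (px).
#' @param background background level (a.u.).
#' @param peak spot peak amplitude above background (a.u.).
#' @param read_noise_sd additive Gaussian noise sd (a.u.); 0 disables.
#' @param shot_noise apply Poisson noise to the noiseless image?
#' @param seed seed for the noise draws.
#' @return An object of class `muc3_stack`: list of frame matrices
#'   (rows = y, columns = x), pixel/origin metadata and `ground_truth`.
#' @export
render_frames <- function(run, pixel_size = 4, psf_sigma = 1.25,
                          background = 100, peak = 400,
                          read_noise_sd = 3, shot_noise = TRUE, seed = 1) {
  stopifnot(inherits(run, "muc3_run"), pixel_size > 0, psf_sigma > 0)
  tr <- run$tracks
  if (!nrow(tr)) stop("empty run: nothing to render")
  g <- run$geometry
  pad <- 6 * psf_sigma * pixel_size
  x0 <- -(g$reservoir_mouth_x + g$reservoir_depth) - pad
  y0 <- -g$loading_half_height - pad
  nxp <- ceiling((2 * (g$reservoir_mouth_x + g$reservoir_depth) + 2 * pad) / pixel_size)
  nyp <- ceiling((2 * g$loading_half_height + 2 * pad) / pixel_size)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  hw <- ceiling(4 * psf_sigma)              # half-width of the stamped window
  off <- -hw:hw
  frames <- vector("list", max(tr$frame))
  for (f in seq_along(frames)) {
    img <- matrix(background, nyp, nxp)
    d <- tr[tr$frame == f, ]
    cx <- (d$x_um - x0) / pixel_size + 0.5  # pixel centres at integer coords
    cy <- (d$y_um - y0) / pixel_size + 0.5
    for (i in seq_len(nrow(d))) {
      jx <- round(cx[i]) + off
      jy <- round(cy[i]) + off
      ok_x <- jx >= 1 & jx <= nxp
      ok_y <- jy >= 1 & jy <= nyp
      gx <- exp(-(jx[ok_x] - cx[i])^2 / (2 * psf_sigma^2))
      gy <- exp(-(jy[ok_y] - cy[i])^2 / (2 * psf_sigma^2))
      img[jy[ok_y], jx[ok_x]] <- img[jy[ok_y], jx[ok_x]] + peak * (gy %o% gx)
    }
    if (shot_noise)
      img <- matrix(stats::rpois(length(img), img), nyp, nxp)
    if (read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, read_noise_sd), nyp, nxp)
    frames[[f]] <- img
  }

  structure(list(frames = frames, pixel_size = pixel_size,
                 origin = c(x0, y0), psf_sigma = psf_sigma,
                 background = background, dt = run$dt,
                 ground_truth = tr),
            class = "muc3_stack")
}

#' @export
print.muc3_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<muc3_stack> %d frames of %d x %d px (%g um/px), dt %g min\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$dt))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale; intensities are clipped to
#' `[0, 65535]`.
#'
#' @param stack a `muc3_stack` (or plain list of matrices).
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a list of numeric matrices on the original intensity scale.
#' @export
write_stack <- function(stack, path) {
  frames <- if (inherits(stack, "muc3_stack")) stack$frames else stack
  imgs <- lapply(frames, function(m) pmin(pmax(m, 0), 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * 65535)
}
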