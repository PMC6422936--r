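#' Estimate a diffusion coefficient from molecular weight
#'
#' Uses the Stokes-Einstein relation `D = kT / (6 * pi * eta * r)` with an
#' empirical hydrodynamic radius `r = radius_coefficient * MW^(1/3)`.  The
#' default `radius_coefficient` of 0.066 nm Da^-1/3 is the usual globular
#' scaling; it is exposed so the gradient-formation behaviour can be probed
#' under different radius laws.
#'
#' @param molecular_weight molecular weight (Da).
#' @param temperature absolute temperature (K); default 310 K (37 C).
#' @param viscosity dynamic viscosity (Pa s); default water at 37 C.
#' @param radius_coefficient hydrodynamic radius prefactor (nm Da^-1/3).
#' @return Diffusion coefficient in um^2/s.
#' @examples
#' estimate_diffusion_coefficient(438) # fMLP
#' estimate_diffusion_coefficient(336) # LTB4
#' @export
estimate_diffusion_coefficient <- function(molecular_weight,
                                           temperature = 310,
                                           viscosity = 6.913e-4,
                                           radius_coefficient = 0.066) {
  if (any(c(molecular_weight, temperature, viscosity, radius_coefficient) <= 0))
    stop("all arguments to estimate_diffusion_coefficient() must be positive")
  kB <- 1.380649e-23                              # J/K
  r_m <- radius_coefficient * molecular_weight^(1 / 3) * 1e-9
  d_m2s <- kB * temperature / (6 * pi * viscosity * r_m)
  d_m2s * 1e12                                    # m^2/s -> um^2/s
}

#' Solve chemoattractant diffusion along a migration channel
#'
#' Integrates the 1-D diffusion equation `dc/dt = D d2c/dx2` along a
#' migration channel.  `x = 0` is the reservoir mouth (held at the reservoir
#' concentration for t > 0) and `x = L` the loading-channel mouth.  With the
#' `"sink"` boundary the loading end is held at zero (the loading channel is
#' bathed in a media volume orders of magnitude larger than a reservoir);
#' `"finite_bath"` instead couples the loading end to a well-mixed bath of
#' volume `bath_volume_uL` fed by all `n_channels` channels of that side.
#'
#' Time stepping is Crank-Nicolson with two implicit-Euler start-up steps to
#' damp the boundary discontinuity at t = 0 (Rannacher start-up), making the
#' scheme unconditionally stable and free of over/undershoot.  An explicit
#' scheme is available for comparison and errors out when its stability
#' criterion `D dt / dx^2 <= 1/2` is violated.
#'
#' @param spec a [chemoattractant_spec()].
#' @param geometry a [device_geometry()].
#' @param boundary_model `"sink"` (default) or `"finite_bath"`.
#' @param dx spatial step (um); must divide the channel length.
#' @param dt time step (s).
#' @param t_end simulated duration (min).
#' @param scheme `"crank_nicolson"` (default) or `"explicit"`.
#' @param bath_volume_uL well-mixed bath volume for `"finite_bath"` (uL).
#' @param record_every interval (min) at which profiles are stored.
#' @return An object of class `muc3_field` with elements `x` (um from the
#'   reservoir mouth), `t_min`, and `conc`, an `length(x) x length(t_min)`
#'   matrix of concentrations (nM).
#' @examples
#' f <- solve_channel_diffusion(chemoattractant_spec("fMLP", 438, 10),
#'                              device_geometry(), t_end = 30)
#' gradient_formation_time(f)
#' @export
solve_channel_diffusion <- function(spec, geometry = device_geometry(),
                                    boundary_model = c("sink", "finite_bath"),
                                    dx = 10, dt = 1, t_end = 300,
                                    scheme = c("crank_nicolson", "explicit"),
                                    bath_volume_uL = 4000,
                                    record_every = 1) {
  boundary_model <- match.arg(boundary_model)
  scheme <- match.arg(scheme)
  L <- geometry$channel_length
  if (abs(L / dx - round(L / dx)) > 1e-9)
    stop("dx must divide the channel length")
  stopifnot(dt > 0, t_end > 0, record_every > 0)

  D <- spec$diffusion_coefficient           # um^2/s
  c0 <- spec$reservoir_concentration
  nx <- round(L / dx) + 1L
  x <- seq(0, L, length.out = nx)
  r <- D * dt / dx^2
  if (scheme == "explicit" && r > 0.5)
    stop(sprintf(paste("explicit scheme unstable: stability criterion",
                       "D*dt/dx^2 <= 1/2 violated (D*dt/dx^2 = %.3f);",
                       "reduce dt or use scheme = 'crank_nicolson'"), r))

  n_steps <- ceiling(t_end * 60 / dt)
  rec_steps <- max(1L, round(record_every * 60 / dt))
  t_out <- c(0, seq_len(floor(n_steps / rec_steps)) * rec_steps * dt / 60)
  conc <- matrix(0, nx, length(t_out))

  cc <- rep(0, nx)
  c_bath <- 0
  cc[1] <- c0                                # reservoir boundary for t > 0
  # finite_bath: flux from n_channels channels into the bath
  area <- geometry$channel_width^2           # um^2 per channel
  bath_vol <- bath_volume_uL * 1e9           # uL -> um^3

  ni <- nx - 2L                              # interior nodes
  step_implicit <- function(cc, theta) {
    # (I - theta*r*T) c_new = c_old + (1-theta)*r*T c_old + boundary terms
    b <- cc[2:(nx - 1)]
    if (theta < 1) {
      lap <- cc[1:(nx - 2)] - 2 * cc[2:(nx - 1)] + cc[3:nx]
      b <- b + (1 - theta) * r * lap
    }
    b[1] <- b[1] + theta * r * cc[1]
    b[ni] <- b[ni] + theta * r * cc[nx]
    cc[2:(nx - 1)] <- thomas_tridiag(-theta * r, 1 + 2 * theta * r, -theta * r, b)
    cc
  }

  col <- 1L
  for (s in seq_len(n_steps)) {
    if (scheme == "explicit") {
      lap <- cc[1:(nx - 2)] - 2 * cc[2:(nx - 1)] + cc[3:nx]
      cc[2:(nx - 1)] <- cc[2:(nx - 1)] + r * lap
    } else {
      theta <- if (s <= 2L) 1 else 0.5       # Rannacher start-up
      cc <- step_implicit(cc, theta)
    }
    if (boundary_model == "finite_bath") {
      flux <- D * (cc[nx - 1] - cc[nx]) / dx * area * geometry$n_channels # nM um^3/s
      c_bath <- c_bath + flux * dt / bath_vol
      cc[nx] <- c_bath
    } else {
      cc[nx] <- 0
    }
    if (s %% rec_steps == 0L) {
      col <- col + 1L
      conc[, col] <- cc
    }
  }

  structure(list(x = x, t_min = t_out, conc = conc, spec = spec,
                 boundary_model = boundary_model, dx = dx, dt = dt,
                 channel_length = L),
            class = "muc3_field")
}

## Constant-coefficient tridiagonal solve (Thomas algorithm).
thomas_tridiag <- function(a, b, c, d) {
  n <- length(d)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c / b
  dp[1] <- d[1] / b
  for (i in 2:n) {
    m <- b - a * cp[i - 1]
    cp[i] <- c / m
    dp[i] <- (d[i] - a * dp[i - 1]) / m
  }
  out <- numeric(n)
  out[n] <- dp[n]
  for (i in (n - 1):1) out[i] <- dp[i] - cp[i] * out[i + 1]
  out
}

#' @export
print.muc3_field <- function(x, ...) {
  cat(sprintf("<muc3_field> %s, %s boundary: %d x-nodes (0..%g um), t 0..%g min\n",
              x$spec$name, x$boundary_model, length(x$x),
              max(x$x), max(x$t_min)))
  invisible(x)
}

#' @export
as.data.frame.muc3_field <- function(x, ...) {
  data.frame(x_um = rep(x$x, times = length(x$t_min)),
             t_min = rep(x$t_min, each = length(x$x)),
             conc_nM = as.vector(x$conc))
}

#' Kymograph plot of a gradient field
#'
#' @param x a `muc3_field`.
#' @param ... passed to [graphics::image()].
#' @export
plot.muc3_field <- function(x, ...) {
  graphics::image(x$t_min, x$x, t(x$conc),
                  xlab = "time (min)", ylab = "x from reservoir (um)",
                  main = sprintf("%s gradient (nM)", x$spec$name),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

## Steady-state profile implied by the field's boundary model.
steady_profile <- function(field) {
  c0 <- field$spec$reservoir_concentration
  cL <- if (field$boundary_model == "sink") 0 else
    field$conc[length(field$x), length(field$t_min)]
  c0 + (cL - c0) * field$x / field$channel_length
}

#' Time for a gradient to form
#'
#' Earliest recorded time at which the concentration profile deviates from
#' its steady state by at most `tolerance` of the reservoir concentration
#' (uniformly in x).  Returns `Inf` if the criterion is never met within the
#' solved interval.
#'
#' @param field a `muc3_field` from [solve_channel_diffusion()].
#' @param tolerance maximum relative deviation; default 0.05.
#' @return Formation time in minutes (possibly 0 or `Inf`).
#' @export
gradient_formation_time <- function(field, tolerance = 0.05) {
  if (!inherits(field, "muc3_field") || length(field$t_min) == 0)
    stop("field must be a non-empty muc3_field")
  c0 <- field$spec$reservoir_concentration
  if (c0 <= 0) return(0)
  css <- steady_profile(field)
  dev <- apply(abs(field$conc - css), 2, max) / c0
  hit <- which(dev <= tolerance)
  if (!length(hit)) return(Inf)
  field$t_min[hit[1]]
}

#' Gradient slope along the channel
#'
#' Ordinary least-squares slope of `c(x, t)` against `x` over the whole
#' channel at the recorded time nearest `t`.
#'
#' @param field a `muc3_field`.
#' @param t time (min); must lie within the solved interval.
#' @return Slope in nM/um (negative: concentration falls away from the
#'   reservoir).
#' @export
gradient_slope <- function(field, t) {
  if (t < min(field$t_min) - 1e-9 || t > max(field$t_min) + 1e-9)
    stop("t outside the solved time range")
  j <- which.min(abs(field$t_min - t))
  cc <- field$conc[, j]
  x <- field$x
  sum((x - mean(x)) * (cc - mean(cc))) / sum((x - mean(x))^2)
}

#' Percent difference between two normalized gradient slopes
#'
#' Each field is normalized to its own reservoir concentration before the
#' slopes are compared, so attractants loaded at different concentrations
#' are compared on gradient *shape*.  Returns
#' `100 * |s_a - s_b| / mean(|s_a|, |s_b|)`; two flat fields compare as 0.
#'
#' @param field_a,field_b `muc3_field` objects over the same channel length.
#' @param t time (min) at which to compare.
#' @return Percent difference (>= 0).
#' @export
slope_similarity <- function(field_a, field_b, t) {
  if (!isTRUE(all.equal(field_a$channel_length, field_b$channel_length)))
    stop("fields must share the channel geometry")
  norm_slope <- function(f) {
    c0 <- f$spec$reservoir_concentration
    if (c0 <= 0) return(0)
    gradient_slope(f, t) / c0
  }
  sa <- norm_slope(field_a); sb <- norm_slope(field_b)
  m <- mean(c(abs(sa), abs(sb)))
  if (m == 0) return(0)
  100 * abs(sa - sb) / m
}

#' Concentrations and gradient steepness at a device position
#'
#' Maps the 1-D channel fields onto the 2-D device.  Inside a migration
#' channel the field is interpolated at the position's axial coordinate;
#' inside a maze rung the concentration is the channel value at the rung's
#' axial position and the local gradient magnitude is divided by the
#' geometry's `maze_attenuation`; inside the loading channel the
#' channel-mouth values are returned with zero gradient; inside a reservoir
#' the reservoir concentration is returned with zero gradient.  A field only
#' reaches positions on its own side of the device: on the opposite side its
#' concentration is the mouth value (~0 under the sink boundary).
#'
#' @param fields named list with elements `fmlp` and `ltb4`, each a
#'   `muc3_field` (the fmlp field occupies the +x side).
#' @param geometry a [device_geometry()].
#' @param position numeric length-2 vector `c(x, y)` in um.
#' @param t time (min).
#' @return `data.frame` with one row per attractant: `concentration` (nM)
#'   and `gradient` (nM/um, magnitude of the local steepness).
#' @export
concentration_lookup <- function(fields, geometry, position, t) {
  stopifnot(length(position) == 2, all(c("fmlp", "ltb4") %in% names(fields)))
  region <- point_region(geometry, position[1], position[2]) # errors if outside
  side <- if (grepl("fmlp$", region)) "fmlp" else
    if (grepl("ltb4$", region)) "ltb4" else "loading"
  u <- abs(position[1]) - geometry$mouth_x       # axial distance from mouth
  xf <- geometry$channel_length - u              # field coordinate (0 = reservoir)

  one <- function(att) {
    f <- fields[[att]]
    j <- which.min(abs(f$t_min - t))
    cc <- f$conc[, j]
    slope <- abs(gradient_slope(f, t))
    interp <- function(xq) stats::approx(f$x, cc, xout = xq, rule = 2)$y
    if (side == "loading" || att != side) {
      c(interp(f$channel_length), 0)             # mouth value, no local gradient
    } else if (startsWith(region, "reservoir")) {
      c(f$spec$reservoir_concentration, 0)
    } else if (startsWith(region, "maze")) {
      ur <- geometry$rung_positions[which.min(abs(geometry$rung_positions - u))]
      c(interp(geometry$channel_length - ur), slope / geometry$maze_attenuation)
    } else {
      c(interp(xf), slope)
    }
  }
  res <- t(vapply(c("fmlp", "ltb4"), one, numeric(2)))
  data.frame(attractant = c("fmlp", "ltb4"),
             concentration = res[, 1], gradient = res[, 2],
             row.names = NULL)
}
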