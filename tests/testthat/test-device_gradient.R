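test_that("Stokes-Einstein estimate is monotone in molecular weight and matches the closed form", {
  d438 <- estimate_diffusion_coefficient(438)
  d336 <- estimate_diffusion_coefficient(336)
  d10k <- estimate_diffusion_coefficient(10000)
  expect_gt(d336, d438)        # lighter molecule diffuses faster
  expect_gt(d438, d10k)        # dextran tracer much slower
  # closed form evaluated by hand: kT/(6 pi eta r), r = 0.066 * 438^(1/3) nm
  expect_equal(d438, 655.3, tolerance = 1e-3)
  expect_equal(d336, 715.8, tolerance = 1e-3)
  expect_error(estimate_diffusion_coefficient(-1), "positive")
  expect_error(estimate_diffusion_coefficient(438, viscosity = 0), "positive")
})

test_that("solver matches the analytic Fourier-series solution on a 90-interval grid", {
  spec <- chemoattractant_spec("fMLP", 438, 10)
  f <- solve_channel_diffusion(spec, fixture_geometry(), dx = 10, dt = 1,
                               t_end = 300)
  expect_equal(length(f$x), 91L)
  for (t in c(1, 5, 15, 60, 300)) {
    j <- which.min(abs(f$t_min - t))
    exact <- series_solution(f$x, t, spec$diffusion_coefficient, 900, 10)
    err <- max(abs(f$conc[, j] - exact)) / 10
    expect_lt(err, 1e-3)
  }
})

test_that("solver field stays within physical bounds with no over/undershoot", {
  spec <- chemoattractant_spec("LTB4", 336, 100)
  f <- solve_channel_diffusion(spec, fixture_geometry(), t_end = 300)
  expect_gte(min(f$conc), -1e-9)
  expect_lte(max(f$conc), 100 + 1e-9)
  # boundary held at reservoir concentration for all t > 0
  expect_true(all(f$conc[1, -1] == 100))
})

test_that("zero reservoir concentration gives an identically zero field", {
  f <- solve_channel_diffusion(chemoattractant_spec("blank", 438, 0),
                               fixture_geometry(), t_end = 30)
  expect_true(all(f$conc == 0))
  expect_equal(gradient_formation_time(f), 0)
})

test_that("steady state is linear: midpoint at half the reservoir value under the sink boundary", {
  spec <- chemoattractant_spec("fMLP", 438, 10)
  f <- solve_channel_diffusion(spec, fixture_geometry(), t_end = 300)
  prof <- f$conc[, ncol(f$conc)]
  lin <- 10 * (1 - f$x / 900)
  expect_lt(max(abs(prof - lin)) / 10, 0.005)   # < 0.5% of reservoir conc
  expect_equal(prof[f$x == 450], 5, tolerance = 0.01)
})

test_that("formation time criterion behaves: zero at steady start, monotone in D, stable at 300 min", {
  geom <- fixture_geometry()
  # formation time is monotone non-increasing in D over a 5-point sweep
  tf <- vapply(c(100, 200, 400, 800, 1600), function(D) {
    f <- solve_channel_diffusion(
      chemoattractant_spec("x", 438, 10, diffusion_coefficient = D),
      geom, t_end = 120)
    gradient_formation_time(f)
  }, numeric(1))
  expect_true(all(diff(tf) <= 0))
  # doubling D shortens formation
  expect_lt(tf[2], tf[1])
  # the default fMLP field still satisfies the criterion at t = 300 min
  f <- solve_channel_diffusion(chemoattractant_spec("fMLP", 438, 10),
                               geom, t_end = 300)
  tform <- gradient_formation_time(f)
  c0 <- 10
  css <- 10 * (1 - f$x / 900)
  dev300 <- max(abs(f$conc[, which.min(abs(f$t_min - 300))] - css)) / c0
  expect_lte(dev300, 0.05)
  expect_lt(tform, 300)
  # a field that never reaches steady state returns Inf
  fshort <- solve_channel_diffusion(
    chemoattractant_spec("slow", 438, 10, diffusion_coefficient = 1),
    geom, t_end = 5)
  expect_identical(gradient_formation_time(fshort), Inf)
})

test_that("gradient_slope recovers the steady-state slope and errors out of range", {
  spec <- chemoattractant_spec("fMLP", 438, 10)
  f <- solve_channel_diffusion(spec, fixture_geometry(), t_end = 300)
  s <- gradient_slope(f, 300)
  expect_equal(abs(s), 10 / 900, tolerance = 1e-3)
  # independent regression oracle at t = 15 min on the solver's own profile
  j <- which.min(abs(f$t_min - 15))
  fit <- stats::lm(f$conc[, j] ~ f$x)
  expect_equal(s15 <- gradient_slope(f, 15), unname(coef(fit)[2]),
               tolerance = 1e-10)
  expect_error(gradient_slope(f, 400), "range")
  # uniform field has zero slope
  f0 <- solve_channel_diffusion(chemoattractant_spec("blank", 438, 0),
                                fixture_geometry(), t_end = 10)
  expect_equal(gradient_slope(f0, 10), 0)
})

test_that("normalized slope similarity: identical fields 0%, fMLP vs LTB4 <= 5%, scale-invariant", {
  ff <- fixture_fields()
  expect_equal(slope_similarity(ff$fmlp, ff$fmlp, 300), 0)
  expect_lte(slope_similarity(ff$fmlp, ff$ltb4, 300), 5)
  # doubling the concentration does not change the normalized slope
  f2 <- solve_channel_diffusion(chemoattractant_spec("fMLP2", 438, 20),
                                fixture_geometry(), t_end = 60)
  f1 <- solve_channel_diffusion(chemoattractant_spec("fMLP", 438, 10),
                                fixture_geometry(), t_end = 60)
  expect_lt(slope_similarity(f1, f2, 60), 1e-9)
})

test_that("explicit scheme rejects unstable discretisations by naming the criterion", {
  spec <- chemoattractant_spec("fMLP", 438, 10)
  expect_error(
    solve_channel_diffusion(spec, fixture_geometry(), dx = 10, dt = 1,
                            scheme = "explicit", t_end = 1),
    "D\\*dt/dx\\^2")
  # a stable explicit setting runs and roughly agrees with Crank-Nicolson
  fe <- solve_channel_diffusion(spec, fixture_geometry(), dx = 10, dt = 0.05,
                                scheme = "explicit", t_end = 10)
  fc <- solve_channel_diffusion(spec, fixture_geometry(), dx = 10, dt = 1,
                                t_end = 10)
  expect_lt(max(abs(fe$conc[, ncol(fe$conc)] - fc$conc[, ncol(fc$conc)])) / 10,
            1e-3)
  expect_error(solve_channel_diffusion(spec, fixture_geometry(), dx = 7),
               "divide")
})

test_that("finite-bath boundary accumulates a small loading-side concentration", {
  spec <- chemoattractant_spec("fMLP", 438, 10)
  fb <- solve_channel_diffusion(spec, fixture_geometry(),
                                boundary_model = "finite_bath",
                                bath_volume_uL = 0.01, t_end = 120)
  expect_gt(fb$conc[length(fb$x), ncol(fb$conc)], 0)
  # a 4-mL bath is effectively a sink
  fs <- solve_channel_diffusion(spec, fixture_geometry(), t_end = 120)
  fb2 <- solve_channel_diffusion(spec, fixture_geometry(),
                                 boundary_model = "finite_bath", t_end = 120)
  expect_lt(max(abs(fb2$conc - fs$conc)) / 10, 1e-3)
})

test_that("concentration_lookup maps fields onto the device with maze attenuation", {
  geom <- fixture_geometry()
  ff <- fixture_fields()
  # reservoir mouth: reservoir concentration
  res <- concentration_lookup(ff, geom, c(960, 0), 300)
  expect_equal(res$concentration[res$attractant == "fmlp"], 10)
  # same axial position, in-channel vs in-maze: gradient 10-fold weaker
  yc <- geom$channel_centers_y
  in_chan <- concentration_lookup(ff, geom, c(50 + 450, yc[5]), 300)
  in_maze <- concentration_lookup(ff, geom, c(50 + 450, (yc[5] + yc[6]) / 2), 300)
  g_chan <- in_chan$gradient[in_chan$attractant == "fmlp"]
  g_maze <- in_maze$gradient[in_maze$attractant == "fmlp"]
  expect_equal(g_maze, g_chan / geom$maze_attenuation)
  # loading channel centre under the sink boundary: ~0 concentration
  load <- concentration_lookup(ff, geom, c(0, 0), 300)
  expect_lt(max(load$concentration), 0.05)
  expect_equal(load$gradient, c(0, 0))
  expect_error(concentration_lookup(ff, geom, c(5000, 0), 300), "outside")
})

test_that("geometry regions are disjoint and labelled toward the distal region", {
  geom <- fixture_geometry()
  yc <- geom$channel_centers_y
  pts <- data.frame(
    x = c(0, 55, 950, 1000, -1000, 50 + 450, 50, -50),
    y = c(0, yc[3], yc[3], 100, -100, (yc[5] + yc[6]) / 2, yc[2], yc[2]),
    want = c("loading", "channel_fmlp", "reservoir_fmlp", "reservoir_fmlp",
             "reservoir_ltb4", "maze_fmlp", "channel_fmlp", "channel_ltb4"))
  got <- muc3:::point_region(geom, pts$x, pts$y)
  expect_equal(got, pts$want)
  # outside the device errors
  expect_error(muc3:::point_region(geom, 60, 0), "outside")
})
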