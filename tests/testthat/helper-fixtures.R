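# Shared fixtures. Gradient fields are solved once per test run; simulations
# at reduced cell counts keep the suite fast while leaving the acceptance
# checks at full scale in test-acceptance.R.

fixture_geometry <- function() device_geometry()

# fields over 300 min at the default discretisation (solved lazily, cached)
.fixture_env <- new.env()
fixture_fields <- function(t_end = 300) {
  key <- paste0("f", t_end)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- default_fields(t_end = t_end)
  .fixture_env[[key]]
}

# analytic Fourier-series solution of 1-D diffusion with fixed boundaries
# c(0,t)=c0, c(L,t)=0, c(x,0)=0 -- the independent oracle for the solver
series_solution <- function(x, t_min, D, L, c0, n_terms = 2000) {
  t_s <- t_min * 60
  n <- seq_len(n_terms)
  cc <- c0 * (1 - x / L)
  for (xi in seq_along(x)) {
    s <- sum(2 * c0 / (n * pi) * sin(n * pi * x[xi] / L) *
               exp(-n^2 * pi^2 * D * t_s / L^2))
    cc[xi] <- cc[xi] - s
  }
  pmax(cc, 0 - 1e-12)
}

# hand-built track table on the shared schema
make_track <- function(x, y = rep(0, length(x)), dt = 2.5, cell_id = 1L,
                       region = NULL) {
  tr <- data.frame(cell_id = cell_id, frame = seq_along(x),
                   t_min = (seq_along(x) - 1) * dt, x_um = x, y_um = y)
  if (!is.null(region)) tr$region <- region
  tr
}
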