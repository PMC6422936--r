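## Scalar metrics a calibration can target, extracted from simulated runs.
calib_metric <- function(runs_dual, runs_spont, name) {
  mm <- function(rs, f) mean(vapply(rs, f, numeric(1)))
  switch(name,
    pct_fmlp = mm(runs_dual, function(r)
      migration_metrics(r)$endpoint_pct[["reservoir_fmlp"]]),
    pct_ltb4 = mm(runs_dual, function(r)
      migration_metrics(r)$endpoint_pct[["reservoir_ltb4"]]),
    rate_fmlp = mm(runs_dual, function(r)
      migration_metrics(r)$rate_pct_per_h[["reservoir_fmlp"]]),
    rate_ltb4 = mm(runs_dual, function(r)
      migration_metrics(r)$rate_pct_per_h[["reservoir_ltb4"]]),
    vel_fmlp = mm(runs_dual, function(r)
      migration_metrics(r)$velocity_mean[["fmlp"]]),
    vel_ltb4 = mm(runs_dual, function(r)
      migration_metrics(r)$velocity_mean[["ltb4"]]),
    decision_ratio = {
      pf <- mm(runs_dual, function(r)
        migration_metrics(r)$endpoint_pct[["reservoir_fmlp"]])
      pl <- mm(runs_dual, function(r)
        migration_metrics(r)$endpoint_pct[["reservoir_ltb4"]])
      decision_ratio(pf, pl)
    },
    spontaneous_pct = mm(runs_spont, spontaneous_fraction),
    stop("unknown calibration metric: ", name))
}

#' Calibrate preset parameters against target metrics by grid search
#'
#' Evaluates every point of a parameter grid by simulating `n_replicates`
#' runs and minimising the summed squared relative error between the
#' simulated and target metrics.  Deterministic given `seed` (replicate
#' seeds are `seed + 1:n_replicates`).  Used to produce the packaged
#' presets from the published per-condition summary statistics.
#'
#' @param base_preset starting [priming_preset()]; non-searched parameters
#'   keep its values.
#' @param targets named numeric vector; names from `pct_fmlp`, `pct_ltb4`,
#'   `rate_fmlp`, `rate_ltb4`, `vel_fmlp`, `vel_ltb4`, `decision_ratio`,
#'   `spontaneous_pct`.
#' @param search_grid named list of candidate values per free parameter
#'   (preset field names).
#' @param n_replicates simulated replicates per grid point.
#' @param n_cells,duration,dt,geometry,fields forwarded to
#'   [simulate_experiment()]; fields are solved once when needed.
#' @param seed base seed.
#' @return List with `preset` (best), `achieved` (its metrics), `loss`, and
#'   the full `grid` table of losses.
#' @export
calibrate_preset <- function(base_preset, targets, search_grid,
                             n_replicates = 3, n_cells = 300,
                             duration = 300, dt = 2.5,
                             geometry = device_geometry(), fields = NULL,
                             seed = 1) {
  stopifnot(inherits(base_preset, "muc3_preset"),
            length(targets) >= 1, !is.null(names(targets)),
            all(is.finite(targets)))
  if (!length(search_grid) || !all(lengths(search_grid) >= 1))
    stop("search_grid must contain at least one candidate per parameter")
  bad <- setdiff(names(search_grid), names(unclass(base_preset)))
  if (length(bad)) stop("unknown preset parameters: ", paste(bad, collapse = ", "))

  need_dual <- any(names(targets) != "spontaneous_pct")
  need_spont <- "spontaneous_pct" %in% names(targets)
  if (need_dual && is.null(fields))
    fields <- default_fields(geometry, t_end = duration)

  grid <- expand.grid(search_grid, KEEP.OUT.ATTRS = FALSE)
  losses <- numeric(nrow(grid))
  achieved_all <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    p <- unclass(base_preset)
    for (nm in names(search_grid)) p[[nm]] <- grid[gi, nm]
    cand <- do.call(priming_preset, p)
    runs_dual <- if (need_dual) lapply(seq_len(n_replicates), function(k)
      simulate_experiment(cand, geometry, fields, n_cells = n_cells,
                          duration = duration, dt = dt, seed = seed + k)) else NULL
    runs_spont <- if (need_spont) lapply(seq_len(n_replicates), function(k)
      simulate_experiment(cand, geometry, NULL, n_cells = n_cells,
                          duration = duration, dt = dt, seed = seed + k)) else NULL
    ach <- vapply(names(targets), function(nm)
      calib_metric(runs_dual, runs_spont, nm), numeric(1))
    achieved_all[[gi]] <- ach
    losses[gi] <- sum(((ach - targets) / ifelse(targets != 0, targets, 1))^2)
  }
  best <- which.min(losses)
  p <- unclass(base_preset)
  for (nm in names(search_grid)) p[[nm]] <- grid[best, nm]
  list(preset = do.call(priming_preset, p),
       achieved = achieved_all[[best]],
       targets = targets,
       loss = losses[best],
       grid = cbind(grid, loss = losses))
}
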