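#' Two-sample Student's t comparison
#'
#' Unpaired two-sample t-test between two groups of measurements, with the
#' equal-variance (classical Student) form as the default and Welch's
#' correction as an option.  Differences are flagged significant at
#' alpha = 0.05.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param group_a,group_b labels for reporting.
#' @param metric name of the compared quantity.
#' @param var_equal assume equal variances (classical Student's t)?
#' @return An object of class `muc3_comparison` with means, sds, the t
#'   statistic, degrees of freedom, p value and the significance flag.
#' @examples
#' compare_groups(c(9.7, 8.1, 12.4), c(18.1, 25.4, 15.2))
#' @export
compare_groups <- function(values_a, values_b, group_a = "A", group_b = "B",
                           metric = "value", var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  out <- list(group_a = group_a, group_b = group_b, metric = metric,
              mean_a = mean(values_a), sd_a = stats::sd(values_a),
              n_a = length(values_a),
              mean_b = mean(values_b), sd_b = stats::sd(values_b),
              n_b = length(values_b),
              t_statistic = unname(tt$statistic),
              df = unname(tt$parameter),
              p_value = tt$p.value,
              significant = tt$p.value < 0.05,
              var_equal = var_equal)
  class(out) <- "muc3_comparison"
  out
}

#' @export
print.muc3_comparison <- function(x, ...) {
  cat(sprintf("<muc3_comparison> %s: %s (%.3g +/- %.3g, n=%d) vs %s (%.3g +/- %.3g, n=%d)\n",
              x$metric, x$group_a, x$mean_a, x$sd_a, x$n_a,
              x$group_b, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.3f (df %.2f), p = %.4g%s\n", x$t_statistic, x$df,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Bin single-cell velocities into a histogram table
#'
#' Half-open bins `[k*w, (k+1)*w)`; the counts always sum to the number of
#' cells.
#'
#' @param velocities numeric vector (um/min).
#' @param bin_width bin width (um/min).
#' @return `data.frame` with `bin_lo`, `bin_hi`, `count` (empty for empty
#'   input).
#' @export
bin_velocities <- function(velocities, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!length(velocities))
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      count = integer(0)))
  k <- floor(velocities / bin_width)
  tab <- table(k)
  kk <- as.numeric(names(tab))
  data.frame(bin_lo = kk * bin_width, bin_hi = (kk + 1) * bin_width,
             count = as.integer(tab))
}

#' Build a cross-condition report bundle
#'
#' Computes [migration_metrics()] for every run, aggregates per-condition
#' replicate summaries (endpoint percentages, rates, velocity means,
#' classification counts, spontaneous fractions), runs pairwise
#' [compare_groups()] between conditions for each replicated scalar metric,
#' and collects per-side velocity histograms.  Everything is deterministic
#' given the runs.  Optionally writes the machine-readable summary (JSON
#' with run provenance) and tidy CSV tables to `output_dir`.
#'
#' @param runs list of `muc3_run` objects (conditions are taken from each
#'   run's preset label); all runs must share the geometry.
#' @param bin_width velocity histogram bin width (um/min).
#' @param output_dir optional directory for `summary.json`,
#'   `metrics_by_run.csv`, `velocities.csv` and `comparisons.csv`.
#' @param multiple_testing `"none"` (default, matching the original
#'   analysis) or a method accepted by [stats::p.adjust()] applied across
#'   each metric's comparison family.
#' @return An object of class `muc3_report`.
#' @export
build_report <- function(runs, bin_width = 1, output_dir = NULL,
                         multiple_testing = "none") {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, logical(1), "muc3_run")))
  geo <- vapply(runs, function(r)
    paste(r$geometry$channel_length, r$geometry$n_channels,
          r$geometry$channel_pitch), character(1))
  if (length(unique(geo)) != 1) stop("all runs must share the device geometry")

  per_run <- lapply(runs, function(r) {
    m <- migration_metrics(r)
    data.frame(
      label = r$preset$label, condition = r$condition, seed = r$seed,
      preset_hash = r$preset_hash,
      pct_fmlp = m$endpoint_pct[["reservoir_fmlp"]],
      pct_ltb4 = m$endpoint_pct[["reservoir_ltb4"]],
      rate_fmlp = m$rate_pct_per_h[["reservoir_fmlp"]],
      rate_ltb4 = m$rate_pct_per_h[["reservoir_ltb4"]],
      vel_fmlp = m$velocity_mean[["fmlp"]],
      vel_ltb4 = m$velocity_mean[["ltb4"]],
      n_lost_fmlp = m$n_lost[["fmlp"]], n_lost_ltb4 = m$n_lost[["ltb4"]],
      n_osc_fmlp = m$n_oscillatory[["fmlp"]],
      n_osc_ltb4 = m$n_oscillatory[["ltb4"]],
      decision_ratio = m$decision_ratio,
      spontaneous_pct = m$spontaneous_pct)
  })
  by_run <- do.call(rbind, per_run)

  velocities <- do.call(rbind, lapply(seq_along(runs), function(i) {
    v <- migration_metrics(runs[[i]])$velocities
    if (!nrow(v)) return(NULL)
    cbind(label = runs[[i]]$preset$label, seed = runs[[i]]$seed, v)
  }))
  histograms <- if (!is.null(velocities)) {
    sp <- split(velocities$velocity_um_min,
                interaction(velocities$label, velocities$side, drop = TRUE))
    lapply(sp, bin_velocities, bin_width = bin_width)
  } else list()

  scalar_metrics <- c("pct_fmlp", "pct_ltb4", "rate_fmlp", "rate_ltb4",
                      "vel_fmlp", "vel_ltb4", "decision_ratio",
                      "spontaneous_pct")
  labs <- unique(by_run$label)
  comparisons <- list()
  if (length(labs) >= 2) {
    for (met in scalar_metrics) {
      for (i in seq_len(length(labs) - 1)) for (j in (i + 1):length(labs)) {
        va <- by_run[[met]][by_run$label == labs[i]]
        vb <- by_run[[met]][by_run$label == labs[j]]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (length(va) >= 2 && length(vb) >= 2)
          comparisons[[length(comparisons) + 1]] <-
            compare_groups(va, vb, labs[i], labs[j], metric = met)
      }
    }
  }
  comp_tab <- if (length(comparisons)) do.call(rbind, lapply(comparisons, function(cp)
    data.frame(metric = cp$metric, group_a = cp$group_a, group_b = cp$group_b,
               mean_a = cp$mean_a, mean_b = cp$mean_b,
               t = cp$t_statistic, p_value = cp$p_value,
               significant = cp$significant))) else NULL
  if (!is.null(comp_tab) && multiple_testing != "none") {
    comp_tab$p_adjusted <- stats::ave(comp_tab$p_value, comp_tab$metric,
                                      FUN = function(p) stats::p.adjust(p, multiple_testing))
    comp_tab$significant <- comp_tab$p_adjusted < 0.05
  }

  agg <- stats::aggregate(by_run[, intersect(scalar_metrics, names(by_run))],
                          by = list(label = by_run$label, condition = by_run$condition),
                          FUN = function(v) mean(v[is.finite(v)]))
  report <- list(by_run = by_run, condition_means = agg,
                 comparisons = comp_tab, histograms = histograms,
                 provenance = data.frame(label = by_run$label,
                                         seed = by_run$seed,
                                         preset_hash = by_run$preset_hash))
  class(report) <- "muc3_report"

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(by_run, file.path(output_dir, "metrics_by_run.csv"),
                     row.names = FALSE)
    if (!is.null(velocities))
      utils::write.csv(velocities, file.path(output_dir, "velocities.csv"),
                       row.names = FALSE)
    if (!is.null(comp_tab))
      utils::write.csv(comp_tab, file.path(output_dir, "comparisons.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(condition_means = agg, comparisons = comp_tab,
           provenance = report$provenance),
      file.path(output_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.muc3_report <- function(x, ...) {
  cat("<muc3_report>\n")
  cat(sprintf("  %d runs, %d conditions, %d pairwise comparisons\n",
              nrow(x$by_run), length(unique(x$by_run$label)),
              if (is.null(x$comparisons)) 0L else nrow(x$comparisons)))
  print(x$condition_means, digits = 4)
  invisible(x)
}
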