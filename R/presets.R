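#' Construct an LPS-priming preset
#'
#' A preset bundles the motility parameters of one conditioning state
#' (unstimulated, super-low-dose LPS at 1 ng/mL, or high-dose LPS at
#' 100 ng/mL).  Presets are plain immutable value objects: construct a new
#' one rather than editing fields.
#'
#' @param label one of `"unstimulated"`, `"superlow_lps"`, `"high_lps"` (or a
#'   custom label for experimental presets).
#' @param motile_fraction probability that a cell responds to the gradients
#'   and migrates at all (dual-gradient condition).
#' @param spontaneous_fraction probability that a cell is motile in the
#'   absence of any chemoattractant.
#' @param speed_mean_fmlp,speed_sd_fmlp per-cell mean and between-cell sd of
#'   migration speed on the fMLP side (um/min).
#' @param speed_mean_ltb4,speed_sd_ltb4 same for the LTB4 side.
#' @param bias_fmlp,bias_ltb4 dimensionless coupling (>= 0) between the local
#'   normalized gradient steepness and the drift toward that side's
#'   channels/reservoir.
#' @param reversal_prob per-step probability that a cell migrating up a
#'   channel flips its direction of travel.
#' @param maze_entry_weight dimensionless multiplier on the probability of
#'   branching into a maze rung when passing a junction (applied to the
#'   rung's relative gradient steepness, 1/maze_attenuation).
#' @return An object of class `muc3_preset`.
#' @seealso [lps_presets()] for the three packaged calibrated presets.
#' @export
priming_preset <- function(label,
                           motile_fraction,
                           spontaneous_fraction,
                           speed_mean_fmlp, speed_sd_fmlp,
                           speed_mean_ltb4, speed_sd_ltb4,
                           bias_fmlp, bias_ltb4,
                           reversal_prob,
                           maze_entry_weight) {
  probs <- c(motile_fraction = motile_fraction,
             spontaneous_fraction = spontaneous_fraction,
             reversal_prob = reversal_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (any(c(speed_mean_fmlp, speed_sd_fmlp, speed_mean_ltb4, speed_sd_ltb4) < 0))
    stop("speeds must be >= 0")
  if (any(c(bias_fmlp, bias_ltb4, maze_entry_weight) < 0))
    stop("bias and maze weights must be >= 0")
  p <- list(label = label,
            motile_fraction = motile_fraction,
            spontaneous_fraction = spontaneous_fraction,
            speed_mean_fmlp = speed_mean_fmlp, speed_sd_fmlp = speed_sd_fmlp,
            speed_mean_ltb4 = speed_mean_ltb4, speed_sd_ltb4 = speed_sd_ltb4,
            bias_fmlp = bias_fmlp, bias_ltb4 = bias_ltb4,
            reversal_prob = reversal_prob,
            maze_entry_weight = maze_entry_weight)
  class(p) <- "muc3_preset"
  p
}

#' @export
print.muc3_preset <- function(x, ...) {
  cat(sprintf("<muc3_preset> %s (hash %s)\n", x$label, preset_hash(x)))
  cat(sprintf("  motile %.2f, spontaneous %.2f, reversal %.3f, maze weight %.2f\n",
              x$motile_fraction, x$spontaneous_fraction, x$reversal_prob,
              x$maze_entry_weight))
  cat(sprintf("  fMLP side: speed %.2f +/- %.2f um/min, bias %.2f\n",
              x$speed_mean_fmlp, x$speed_sd_fmlp, x$bias_fmlp))
  cat(sprintf("  LTB4 side: speed %.2f +/- %.2f um/min, bias %.2f\n",
              x$speed_mean_ltb4, x$speed_sd_ltb4, x$bias_ltb4))
  invisible(x)
}

#' Packaged LPS-priming presets
#'
#' The three conditioning states shipped with the package:
#' `unstimulated`, `superlow_lps` (1 ng/mL overnight) and `high_lps`
#' (100 ng/mL overnight).  Parameter values were calibrated by grid search
#' (see [calibrate_preset()]) so that the default dual-gradient and
#' no-chemoattractant experiments (500 cells, 300 min, 2.5-min frames)
#' reproduce the published summary statistics of the corresponding wet-lab
#' conditions: endpoint percent migrated per reservoir, maximum 1-h
#' accumulation rates, mean single-cell velocities per side, spontaneous
#' migration fractions, and the trends in non-directional ("lost") and
#' oscillatory classification counts.  Note that `speed_mean_*` are the
#' underlying walk speeds, calibrated so that the *measured* in-channel
#' velocities (which include single-file queueing delays) match the
#' published means; they are therefore slightly above the printed values.
#'
#' @return Named list of three [priming_preset()] objects.
#' @examples
#' names(lps_presets())
#' lps_presets()$unstimulated
#' @export
lps_presets <- function() {
  list(
    unstimulated = priming_preset(
      "unstimulated",
      motile_fraction = 0.13, spontaneous_fraction = 0.105,
      speed_mean_fmlp = 10.9, speed_sd_fmlp = 2.0,
      speed_mean_ltb4 = 10.0, speed_sd_ltb4 = 2.0,
      bias_fmlp = 3.3, bias_ltb4 = 1.4,
      reversal_prob = 0.012, maze_entry_weight = 0.32),
    superlow_lps = priming_preset(
      "superlow_lps",
      motile_fraction = 0.225, spontaneous_fraction = 0.27,
      speed_mean_fmlp = 8.75, speed_sd_fmlp = 1.6,
      speed_mean_ltb4 = 11.4, speed_sd_ltb4 = 1.4,
      bias_fmlp = 9, bias_ltb4 = 16,
      reversal_prob = 0.045, maze_entry_weight = 2.0),
    high_lps = priming_preset(
      "high_lps",
      motile_fraction = 0.17, spontaneous_fraction = 0.16,
      speed_mean_fmlp = 11.2, speed_sd_fmlp = 1.8,
      speed_mean_ltb4 = 8.66, speed_sd_ltb4 = 1.8,
      bias_fmlp = 26, bias_ltb4 = 1.8,
      reversal_prob = 0.008, maze_entry_weight = 0.45)
  )
}

#' Short content hash of a preset (provenance)
#'
#' Polynomial rolling hash over the preset's formatted parameter values;
#' used in run provenance headers and report summaries.
#'
#' @param preset a [priming_preset()].
#' @return 8-character hexadecimal string.
#' @export
preset_hash <- function(preset) {
  stopifnot(inherits(preset, "muc3_preset"))
  s <- paste(vapply(preset, function(v) format(v, digits = 12), character(1)),
             collapse = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
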