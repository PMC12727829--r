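# Concentration matching of standard peptides to endogenous levels and
# assembly of tiered or equal-concentration standard mixtures.

#' Estimate the endogenous-equivalent concentration of a peptide
#'
#' Given a dilution series of the heavy standard spiked into a fixed
#' endogenous background, finds the spike level at which the light/heavy
#' signal ratio equals 1, interpolating linearly in log-log space between
#' the bracketing levels. If the ratio stays above 1 at the highest level
#' the endogenous level exceeds the series and the maximum level is
#' returned with an `"above_range"` flag; symmetrically `"below_range"` at
#' the low end. If no level has a detectable heavy signal the estimate is
#' undetermined.
#'
#' @param level_pg_per_ul Spike levels (pg/ul), need not be sorted.
#' @param light_signal,heavy_signal Linear-scale signals per level.
#' @param levels_ok Optional logical mask restricting the interpolation to
#'   levels inside the linear range (e.g. from a calibration accuracy
#'   rule); defaults to all levels.
#' @return A list with `endogenous_equiv_pg_per_ul` and `flag`
#'   (`"ok"`, `"above_range"`, `"below_range"` or `"undetermined"`).
#' @export
estimate_endogenous_level <- function(level_pg_per_ul, light_signal,
                                      heavy_signal, levels_ok = NULL) {
  if (is.null(levels_ok)) levels_ok <- rep(TRUE, length(level_pg_per_ul))
  usable <- levels_ok & !is.na(heavy_signal) & heavy_signal > 0 &
    !is.na(light_signal) & light_signal > 0
  if (!any(usable)) {
    return(list(endogenous_equiv_pg_per_ul = NA_real_, flag = "undetermined"))
  }
  lev <- level_pg_per_ul[usable]
  ratio <- light_signal[usable] / heavy_signal[usable]
  ord <- order(lev)
  lev <- lev[ord]
  ratio <- ratio[ord]
  if (length(lev) < 2L) {
    return(list(endogenous_equiv_pg_per_ul = NA_real_, flag = "undetermined"))
  }
  lr <- log10(ratio)
  lx <- log10(lev)
  if (all(lr > 0)) {
    warning("light/heavy ratio > 1 at all usable levels; returning max level")
    return(list(endogenous_equiv_pg_per_ul = max(lev), flag = "above_range"))
  }
  if (all(lr < 0)) {
    warning("light/heavy ratio < 1 at all usable levels; returning min level")
    return(list(endogenous_equiv_pg_per_ul = min(lev), flag = "below_range"))
  }
  hit <- which(lr == 0)
  if (length(hit) > 0L) {
    return(list(endogenous_equiv_pg_per_ul = lev[hit[1L]], flag = "ok"))
  }
  i <- which(lr[-length(lr)] * lr[-1L] < 0)[1L]
  x0 <- lx[i] + (0 - lr[i]) * (lx[i + 1L] - lx[i]) / (lr[i + 1L] - lr[i])
  list(endogenous_equiv_pg_per_ul = 10^x0, flag = "ok")
}

#' Assign a concentration tier
#'
#' Assigns the tier nearest to the endogenous-equivalent concentration in
#' log10 space (ties go to the lower tier) and checks the one-order-of-
#' magnitude matching rule `|log10(tier / endogenous)| <= 1`; the
#' candidate-screen threshold of two orders is reported separately.
#'
#' @param endogenous_equiv_pg_per_ul Endogenous-equivalent concentration.
#' @param tiers Ordered tier concentrations in pg/ul; the defaults span
#'   the 10 pg/ul to 2 ng/ul range.
#' @param final_log_tol Final matching tolerance in log10 units.
#' @param screen_log_tol Candidate-screen tolerance in log10 units.
#' @return A list with `assigned_pg_per_ul`, `tier` (index),
#'   `log10_distance`, `within_screen` and `flag` (`TRUE` when the final
#'   one-order rule is violated).
#' @export
assign_tier <- function(endogenous_equiv_pg_per_ul,
                        tiers = c(10, 100, 500, 2000),
                        final_log_tol = 1, screen_log_tol = 2) {
  if (length(tiers) == 0L) stop("configuration error: empty tier list")
  if (is.unsorted(tiers)) stop("tiers must be sorted ascending")
  if (is.na(endogenous_equiv_pg_per_ul) || endogenous_equiv_pg_per_ul <= 0) {
    stop("endogenous-equivalent concentration must be positive")
  }
  d <- abs(log10(tiers / endogenous_equiv_pg_per_ul))
  # ties broken toward the lower tier
  idx <- which(d <= min(d) + 1e-12)[1L]
  list(
    assigned_pg_per_ul = tiers[idx],
    tier = idx,
    log10_distance = d[idx],
    within_screen = d[idx] <= screen_log_tol,
    flag = d[idx] > final_log_tol
  )
}

#' Compose a tiered standard mixture
#'
#' Applies [assign_tier()] to a set of endogenous-equivalent levels.
#'
#' @param endogenous_equiv Named numeric vector of endogenous-equivalent
#'   concentrations (pg/ul) per peptide.
#' @param tiers Tier concentrations, ascending.
#' @param ... Passed to [assign_tier()].
#' @return A `panel_composition` data frame: `peptide`, `pg_per_ul`,
#'   `tier`, `endogenous_equiv_pg_per_ul`, `log10_distance`, `flag`.
#' @export
compose_standard <- function(endogenous_equiv, tiers = c(10, 100, 500, 2000),
                             ...) {
  rows <- lapply(seq_along(endogenous_equiv), function(i) {
    a <- assign_tier(endogenous_equiv[[i]], tiers = tiers, ...)
    data.frame(peptide = names(endogenous_equiv)[i],
               pg_per_ul = a$assigned_pg_per_ul, tier = a$tier,
               endogenous_equiv_pg_per_ul = endogenous_equiv[[i]],
               log10_distance = a$log10_distance, flag = a$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("panel_composition", "data.frame")
  out
}

#' Total peptide mass of a standard mixture
#'
#' Sums the per-peptide amounts over the spiked volume and reports the
#' total in ng. An equal-concentration mixture can be given as a plain
#' numeric vector of per-peptide concentrations (pg/ul).
#'
#' @param composition A composition data frame with a `pg_per_ul` column,
#'   or a numeric vector of per-peptide concentrations in pg/ul.
#' @param volume_ul Spiked volume in ul.
#' @return Total peptide mass in ng.
#' @export
composition_totals <- function(composition, volume_ul = 1) {
  conc <- if (is.data.frame(composition)) composition$pg_per_ul else composition
  if (length(conc) == 0L) return(0)
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("all concentrations must be positive")
  }
  sum(conc) * volume_ul / 1000
}
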