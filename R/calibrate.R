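# Weighted linear calibration, LOD/LOQ from replicate curves, accuracy-based
# LLOQ/ULOQ, and back-calculation with range filtering.
#
# The response variable is the light/heavy signal ratio by default,
# consistent with concentration-matched internal-standard usage; raw light
# signal works identically. LOD = 3.3 * sigma / S and LOQ = 10 * sigma / S,
# where sigma is the standard deviation of the y-intercepts across replicate
# curves and S is the mean slope, so LOQ/LOD = 10/3.3 identically.

#' Fit a calibration line
#'
#' Weighted least squares of response on concentration with 1/x weights
#' (or unweighted). The blank (x = 0) point has an undefined 1/x weight
#' and is excluded from the weighted fit with a warning; it serves only
#' for blank-signal checks. The coefficient of determination is computed
#' on the weighted fit.
#'
#' @param x Nominal concentrations (pg or pg/ul).
#' @param y Responses (light/heavy ratio, linear scale).
#' @param weighting `"one_over_x"` or `"none"`.
#' @return A list with `slope`, `intercept`, `r2` and `n`.
#' @export
fit_curve <- function(x, y, weighting = c("one_over_x", "none")) {
  weighting <- match.arg(weighting)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (weighting == "one_over_x" && any(x == 0)) {
    warning("blank (x = 0) point excluded from the 1/x-weighted fit")
    y <- y[x != 0]
    x <- x[x != 0]
  }
  if (length(unique(x)) < 2L) {
    stop("singular fit: need at least 2 distinct concentrations")
  }
  w <- if (weighting == "one_over_x") 1 / x else rep(1, length(x))
  fit <- stats::lm(y ~ x, weights = w)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       n = length(x))
}

#' LOD and LOQ from replicate calibration curves
#'
#' `LOD = 3.3 * sigma / S`, `LOQ = 10 * sigma / S`, with `sigma` the
#' sample standard deviation of the y-intercepts across replicate curves
#' and `S` the mean slope. This estimates sensitivity from intercept
#' variability rather than blank noise (appropriate when blanks show
#' negligible signal). A non-positive mean slope leaves both limits
#' undefined.
#'
#' @param slopes Per-replicate fitted slopes.
#' @param intercepts Per-replicate fitted intercepts.
#' @return A list with `lod`, `loq`, `sigma_intercept`, `mean_slope` and
#'   `flag`.
#' @export
lod_loq <- function(slopes, intercepts) {
  if (length(slopes) < 2L || length(intercepts) < 2L) {
    stop("need at least 2 replicate curves")
  }
  sigma <- stats::sd(intercepts)
  S <- mean(slopes)
  if (is.na(S) || S <= 0) {
    return(list(lod = NA_real_, loq = NA_real_, sigma_intercept = sigma,
                mean_slope = S, flag = "nonpositive_slope"))
  }
  list(lod = 3.3 * sigma / S, loq = 10 * sigma / S,
       sigma_intercept = sigma, mean_slope = S, flag = "ok")
}

#' Quantifiable range from back-calculation accuracy
#'
#' A calibration level passes when the CV of its back-calculated
#' concentrations across replicates is at most `cv_limit` (20%); if fewer
#' than `min_levels` levels pass, the rule is re-evaluated at
#' `cv_limit_relaxed` (40%). The LLOQ is the lowest and the ULOQ the
#' highest passing level.
#'
#' @param level Nominal concentration per observation.
#' @param back_calc Back-calculated concentration per observation.
#' @param cv_limit Primary accuracy CV limit in percent (inclusive).
#' @param cv_limit_relaxed Relaxed limit applied when fewer than
#'   `min_levels` levels pass the primary rule.
#' @param min_levels Minimum number of passing levels before relaxing.
#' @return A list with `lloq`, `uloq`, `level_cv` (named CV per level),
#'   `cv_limit_used` and `flag`.
#' @export
quant_range <- function(level, back_calc, cv_limit = 20,
                        cv_limit_relaxed = 40, min_levels = 4L) {
  lev_cv <- tapply(back_calc, level, cv, method = "classic")
  lev_cv <- stats::setNames(as.numeric(lev_cv), names(lev_cv))
  lev <- as.numeric(names(lev_cv))
  pass <- !is.na(lev_cv) & lev_cv <= cv_limit
  used <- cv_limit
  if (sum(pass) < min_levels) {
    pass <- !is.na(lev_cv) & lev_cv <= cv_limit_relaxed
    used <- cv_limit_relaxed
  }
  if (!any(pass)) {
    return(list(lloq = NA_real_, uloq = NA_real_, level_cv = lev_cv,
                cv_limit_used = used, flag = "no_passing_level"))
  }
  list(lloq = min(lev[pass]), uloq = max(lev[pass]), level_cv = lev_cv,
       cv_limit_used = used, flag = "ok")
}

#' Back-calculate concentrations from responses
#'
#' Inverts the calibration line, `x = (y - intercept) / slope`, and
#' removes values outside the observed calibrant range with a reason code.
#'
#' @param response Responses to invert.
#' @param curve A fitted curve (list with `slope` and `intercept`, or a
#'   `sil_calibration`).
#' @param observed_range Length-2 numeric `(min, max)` of calibrant
#'   concentrations observed across all samples; values outside are
#'   removed.
#' @return A data frame with `response`, `conc`, `removed` and `reason`
#'   (`"below_range"` / `"above_range"` / `""`).
#' @export
back_calculate <- function(response, curve, observed_range = NULL) {
  slope <- curve$slope
  intercept <- curve$intercept
  if (is.na(slope) || slope == 0) stop("slope must be nonzero")
  conc <- (response - intercept) / slope
  removed <- rep(FALSE, length(conc))
  reason <- rep("", length(conc))
  if (!is.null(observed_range)) {
    lo <- conc < observed_range[1L]
    hi <- conc > observed_range[2L]
    removed <- (lo | hi) & !is.na(conc)
    reason[which(lo)] <- "below_range"
    reason[which(hi)] <- "above_range"
  }
  data.frame(response = response,
             conc = ifelse(removed, NA_real_, conc),
             removed = removed, reason = reason, stringsAsFactors = FALSE)
}

#' Calibrate one peptide from replicate curves
#'
#' Fits one weighted line per replicate, derives LOD/LOQ from the
#' intercept spread and mean slope, back-calculates every calibration
#' point against its own replicate's curve, and determines the LLOQ/ULOQ
#' from the accuracy rule. A curve is reportable when at least
#' `min_levels` levels pass the accuracy rule and the mean coefficient of
#' determination reaches `r2_min`.
#'
#' @param conc Nominal concentrations (one value per observation).
#' @param response Responses (light/heavy ratio by default usage).
#' @param replicate Replicate label per observation.
#' @param weighting Passed to [fit_curve()].
#' @param r2_min Minimal mean r-squared for a reportable curve.
#' @param ... Passed to [quant_range()].
#' @return An object of class `sil_calibration`: `slope` (mean),
#'   `intercept` (mean), `r2` (mean), per-replicate `fits`, `lod`, `loq`,
#'   `lloq`, `uloq`, `level_cv`, `reportable`, `flags`.
#' @export
calibrate_peptide <- function(conc, response, replicate,
                              weighting = "one_over_x", r2_min = 0.98, ...) {
  reps <- unique(replicate)
  if (length(reps) < 2L) stop("need at least 2 replicate curves")
  fits <- lapply(reps, function(r) {
    idx <- replicate == r
    fit_curve(conc[idx], response[idx], weighting = weighting)
  })
  names(fits) <- as.character(reps)
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  intercepts <- vapply(fits, `[[`, numeric(1), "intercept")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  ll <- lod_loq(slopes, intercepts)
  bc <- numeric(length(conc))
  for (r in reps) {
    idx <- which(replicate == r)
    bc[idx] <- (response[idx] - fits[[as.character(r)]]$intercept) /
      fits[[as.character(r)]]$slope
  }
  nz <- conc > 0
  qr <- quant_range(conc[nz], bc[nz], ...)
  n_pass <- sum(!is.na(qr$level_cv) & qr$level_cv <= qr$cv_limit_used)
  structure(
    list(slope = mean(slopes), intercept = mean(intercepts),
         r2 = mean(r2s), fits = fits,
         lod = ll$lod, loq = ll$loq,
         sigma_intercept = ll$sigma_intercept, mean_slope = ll$mean_slope,
         lloq = qr$lloq, uloq = qr$uloq, level_cv = qr$level_cv,
         cv_limit_used = qr$cv_limit_used,
         reportable = n_pass >= 4L && mean(r2s) >= r2_min,
         flags = c(ll$flag, qr$flag)),
    class = "sil_calibration"
  )
}

#' @exportS3Method base::print
print.sil_calibration <- function(x, ...) {
  cat("SIL calibration curve\n")
  cat(sprintf("  slope %.4g, intercept %.4g, r2 %.4f (%d replicates)\n",
              x$slope, x$intercept, x$r2, length(x$fits)))
  cat(sprintf("  LOD %.4g, LOQ %.4g (sigma %.4g, mean slope %.4g)\n",
              x$lod, x$loq, x$sigma_intercept, x$mean_slope))
  cat(sprintf("  LLOQ %.4g, ULOQ %.4g (accuracy CV <= %g%%)\n",
              x$lloq, x$uloq, x$cv_limit_used))
  cat("  reportable:", x$reportable, "\n")
  invisible(x)
}

#' @export
coef.sil_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.sil_calibration <- function(object, response, observed_range = NULL,
                                    ...) {
  back_calculate(response, object, observed_range = observed_range)
}

#' Calibrate a set of peptides
#'
#' Applies [calibrate_peptide()] per peptide of a long calibration series.
#'
#' @param series A data frame with columns `peptide`, `replicate`, `conc`
#'   and `response`.
#' @param ... Passed to [calibrate_peptide()].
#' @return A data frame with one row per peptide: `peptide`, `slope`,
#'   `intercept`, `r2`, `lod`, `loq`, `lloq`, `uloq`, `reportable`.
#' @export
calibrate_peptides <- function(series, ...) {
  rows <- lapply(split(series, series$peptide), function(d) {
    cal <- calibrate_peptide(d$conc, d$response, d$replicate, ...)
    data.frame(peptide = d$peptide[1L], slope = cal$slope,
               intercept = cal$intercept, r2 = cal$r2, lod = cal$lod,
               loq = cal$loq, lloq = cal$lloq, uloq = cal$uloq,
               reportable = cal$reportable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
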