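# Completeness filtering, median ("norm_light") and SIL-ratio ("ratio")
# normalization, CV metrics, quantification-precursor selection, fragment
# distribution profiles, cross-method fold changes and retention-time
# agreement QC. All quantities stay on the linear intensity scale.

#' Data-completeness filter
#'
#' A peptide is retained on a platform when it is detected (non-missing
#' light-channel intensity) in strictly more than `threshold` of the
#' platform's samples; the default threshold is two-thirds.
#'
#' @param table A `quant_table`.
#' @param threshold Detection fraction; retention requires a strictly
#'   greater fraction.
#' @param channel Channel defining detection.
#' @param by_platform Evaluate completeness per platform (default) or over
#'   all samples jointly.
#' @return A data frame with `platform_id` (or `"all"`), `peptide`,
#'   `n_detected`, `n_samples`, `fraction`, `retained`.
#' @export
completeness_filter <- function(table, threshold = 2 / 3, channel = "L",
                                by_platform = TRUE) {
  df <- as.data.frame(table)
  df <- df[df$channel == channel, , drop = FALSE]
  if (!by_platform) df$platform_id <- "all"
  n_samples <- tapply(df$sample_id, df$platform_id,
                      function(x) length(unique(x)))
  if (any(n_samples == 0L) || nrow(df) == 0L) stop("no samples defined")
  df$peptide <- precursor_id(df$modified_seq, df$charge)
  obs <- df[!is.na(df$intensity), , drop = FALSE]
  key <- paste(obs$platform_id, obs$peptide, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(platform_id = obs$platform_id[first],
                    peptide = obs$peptide[first], stringsAsFactors = FALSE)
  grp <- factor(key, levels = key[first])
  out$n_detected <- as.integer(tapply(obs$sample_id, grp,
                                      function(x) length(unique(x))))
  out$n_samples <- as.integer(n_samples[out$platform_id])
  out$fraction <- out$n_detected / out$n_samples
  out$retained <- out$fraction > threshold
  rownames(out) <- NULL
  out
}

#' Median normalization of endogenous quantities
#'
#' Computes one scalar factor per platform as the median of all endogenous
#' (light-channel) intensities in that platform's study-pool runs, and
#' divides every light intensity on the platform by it
#' (`norm_light = light / median(pool light)`).
#'
#' @param table A `quant_table`.
#' @param pool_runs Character vector of run identifiers forming the study
#'   pools.
#' @return A normalized table: `run_id`, `sample_id`, `peptide`,
#'   `platform_id`, `group`, `norm_light`; the per-platform factors are in
#'   the `"median_factors"` attribute.
#' @export
median_normalize <- function(table, pool_runs) {
  df <- as.data.frame(table)
  light <- df[df$channel == "L", , drop = FALSE]
  platforms <- unique(light$platform_id)
  factors <- vapply(platforms, function(p) {
    pool <- light$intensity[light$platform_id == p &
                              light$run_id %in% pool_runs]
    pool <- pool[!is.na(pool)]
    if (length(pool) == 0L) {
      stop("no pool intensities on platform ", p)
    }
    stats::median(pool)
  }, numeric(1))
  names(factors) <- platforms
  out <- data.frame(
    run_id = light$run_id,
    sample_id = light$sample_id,
    peptide = precursor_id(light$modified_seq, light$charge),
    platform_id = light$platform_id,
    group = light$group,
    norm_light = light$intensity / factors[light$platform_id],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "median_factors") <- factors
  out
}

#' SIL-ratio normalization
#'
#' Forms the ratio of the endogenous (light) intensity to the matched
#' heavy internal-standard intensity within the same run, matched by
#' modified sequence and charge (`ratio = light / SIS`). The ratio is
#' emitted where both channels are present and the standard intensity is
#' positive; otherwise it is missing — missingness is data, not failure,
#' and no imputation happens here.
#'
#' @param table A `quant_table` carrying both channels.
#' @return A normalized table: `run_id`, `sample_id`, `peptide`,
#'   `platform_id`, `group`, `light`, `sis`, `ratio`.
#' @export
ratio_normalize <- function(table) {
  df <- as.data.frame(table)
  df$peptide <- precursor_id(df$modified_seq, df$charge)
  light <- df[df$channel == "L", , drop = FALSE]
  heavy <- df[df$channel == "H", c("run_id", "peptide", "intensity")]
  names(heavy)[3L] <- "sis"
  out <- merge(
    light[, c("run_id", "sample_id", "peptide", "platform_id", "group",
              "intensity")],
    heavy, by = c("run_id", "peptide"), all.x = TRUE, sort = FALSE
  )
  names(out)[names(out) == "intensity"] <- "light"
  out$ratio <- ifelse(!is.na(out$light) & !is.na(out$sis) & out$sis > 0,
                      out$light / out$sis, NA_real_)
  rownames(out) <- NULL
  out
}

#' Normalize a quantification table by both strategies
#'
#' Convenience wrapper merging [median_normalize()] and
#' [ratio_normalize()] output on (run, peptide).
#'
#' @param table A `quant_table`.
#' @param pool_runs Study-pool run identifiers for the median factors.
#' @param method `"both"`, `"ratio"` or `"norm_light"`.
#' @return A normalized table with the requested columns.
#' @export
normalize_table <- function(table, pool_runs = NULL,
                            method = c("both", "ratio", "norm_light")) {
  method <- match.arg(method)
  if (method == "ratio") return(ratio_normalize(table))
  if (is.null(pool_runs)) stop("pool_runs required for median normalization")
  nl <- median_normalize(table, pool_runs)
  if (method == "norm_light") return(nl)
  rt <- ratio_normalize(table)
  out <- merge(nl, rt[, c("run_id", "peptide", "light", "sis", "ratio")],
               by = c("run_id", "peptide"), all = TRUE, sort = FALSE)
  attr(out, "median_factors") <- attr(nl, "median_factors")
  out
}

#' Coefficient of variation, robust or classic, in percent
#'
#' The robust CV is the scaled median absolute deviation (normal
#' consistency constant 1.4826) over the median, times 100; the classic CV
#' is the sample standard deviation over the mean, times 100. With fewer
#' than two non-missing values the CV is undefined and reported missing.
#'
#' @param values Positive numeric values on the linear scale.
#' @param method `"robust"` (MAD/median) or `"classic"` (SD/mean).
#' @param mad_constant Scale factor applied to the MAD; set to 1 to drop
#'   the normal-consistency convention.
#' @return CV in percent, or `NA` when undefined.
#' @export
cv <- function(values, method = c("robust", "classic"),
               mad_constant = 1.4826) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  if (method == "robust") {
    100 * stats::mad(v, constant = mad_constant) / stats::median(v)
  } else {
    100 * stats::sd(v) / mean(v)
  }
}

#' CV report for a normalized table
#'
#' Per-peptide robust and classic CVs over a set of runs (typically
#' study-pool replicates).
#'
#' @param normalized A normalized table with a `peptide` column.
#' @param value Name of the value column (`"ratio"` or `"norm_light"`).
#' @param runs Optional run subset.
#' @return A data frame: `peptide`, `cv_robust_pct`, `cv_classic_pct`, `n`.
#' @export
cv_report <- function(normalized, value = "ratio", runs = NULL) {
  df <- normalized
  if (!is.null(runs)) df <- df[df$run_id %in% runs, , drop = FALSE]
  peps <- unique(df$peptide)
  out <- data.frame(peptide = peps, stringsAsFactors = FALSE)
  vals <- split(df[[value]], factor(df$peptide, levels = peps))
  out$cv_robust_pct <- vapply(vals, cv, numeric(1), method = "robust")
  out$cv_classic_pct <- vapply(vals, cv, numeric(1), method = "classic")
  out$n <- vapply(vals, function(x) sum(!is.na(x)), integer(1))
  rownames(out) <- NULL
  out
}

#' Select the quantification precursor per peptide
#'
#' Discards candidate precursors whose study-pool replicate CV is 40% or
#' more (strict `< 40` gate), then selects the most abundant surviving
#' precursor of each peptide (the charge state with the best ionization
#' efficiency). When standard-profile vectors across samples are supplied,
#' precursors of peptides from the same protein are additionally checked
#' for trend agreement (Spearman correlation >= 0 between their profiles);
#' disagreeing peptides are flagged, not dropped.
#'
#' @param candidates A data frame with columns `peptide`, `precursor`,
#'   `pool_cv_pct`, `abundance` and optionally `protein_group`.
#' @param profiles Optional named list (by `precursor`) of standard
#'   profile vectors over the same samples.
#' @param cv_gate CV gate in percent (strict).
#' @return The selected rows with a `trend_flag` column; peptides with no
#'   passing candidate are listed in the `"unquantifiable"` attribute.
#' @export
select_quant_precursor <- function(candidates, profiles = NULL,
                                   cv_gate = 40) {
  pass <- candidates[!is.na(candidates$pool_cv_pct) &
                       candidates$pool_cv_pct < cv_gate, , drop = FALSE]
  unq <- setdiff(unique(candidates$peptide), unique(pass$peptide))
  if (length(unq) > 0L) {
    warning("peptide(s) with no precursor passing the CV gate: ",
            paste(unq, collapse = ", "))
  }
  ord <- order(pass$peptide, -pass$abundance, pass$precursor)
  sel <- pass[ord, , drop = FALSE]
  sel <- sel[!duplicated(sel$peptide), , drop = FALSE]
  sel$trend_flag <- FALSE
  if (!is.null(profiles) && "protein_group" %in% names(sel)) {
    for (pg in unique(sel$protein_group)) {
      idx <- which(sel$protein_group == pg)
      if (length(idx) < 2L) next
      prs <- sel$precursor[idx]
      prs <- prs[prs %in% names(profiles)]
      if (length(prs) < 2L) next
      for (i in seq_len(length(prs) - 1L)) {
        for (j in seq(i + 1L, length(prs))) {
          rho <- suppressWarnings(
            stats::cor(profiles[[prs[i]]], profiles[[prs[j]]],
                       method = "spearman", use = "pairwise.complete.obs"))
          if (!is.na(rho) && rho < 0) {
            sel$trend_flag[sel$precursor %in% c(prs[i], prs[j])] <- TRUE
          }
        }
      }
    }
  }
  rownames(sel) <- NULL
  attr(sel, "unquantifiable") <- unq
  sel
}

#' Fragment intensity distribution profile
#'
#' Within each run, each fragment's intensity is expressed as a percentage
#' of the run's total fragment signal; the profile is the median of these
#' per-run percentages per fragment, restricted to the 12 most intense
#' fragments and rescaled to sum to 100. Working on per-run percentages
#' makes the profile exactly invariant to per-run intensity rescaling.
#'
#' @param fragments A data frame with `fragment_id`, `run_id` and
#'   `intensity` for one precursor.
#' @param max_fragments Number of fragments retained.
#' @return A data frame `fragment_id`, `median_run_percent`, `percent`,
#'   sorted by decreasing contribution; `percent` sums to 100.
#' @export
fragment_distribution <- function(fragments, max_fragments = 12L) {
  fragments <- fragments[!is.na(fragments$intensity), , drop = FALSE]
  if (nrow(fragments) == 0L) stop("no fragments")
  run_total <- tapply(fragments$intensity, fragments$run_id, sum)
  pct_in_run <- 100 * fragments$intensity / run_total[fragments$run_id]
  med <- tapply(pct_in_run, fragments$fragment_id, stats::median)
  med <- sort(med, decreasing = TRUE)
  med <- med[seq_len(min(max_fragments, length(med)))]
  data.frame(fragment_id = names(med),
             median_run_percent = as.numeric(med),
             percent = 100 * as.numeric(med) / sum(med),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-method fold change
#'
#' Per peptide, the median over shared samples of the value in table `a`
#' over the value in table `b`; the cohort summary is the median over
#' peptides. Values close to 1 indicate agreeing quantification scales.
#'
#' @param a,b Normalized tables sharing samples and peptides.
#' @param value Value column compared.
#' @return A list with `per_peptide` (data frame `peptide`,
#'   `median_foldchange`, `n`) and `median_foldchange` (cohort median).
#' @export
cross_method_foldchange <- function(a, b, value = "ratio") {
  m <- merge(a[, c("sample_id", "peptide", value)],
             b[, c("sample_id", "peptide", value)],
             by = c("sample_id", "peptide"), suffixes = c("_a", "_b"))
  va <- m[[paste0(value, "_a")]]
  vb <- m[[paste0(value, "_b")]]
  ok <- !is.na(va) & !is.na(vb) & vb != 0
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0L) stop("no overlapping (sample, peptide) observations")
  fc <- va[ok] / vb[ok]
  per <- tapply(fc, m$peptide, stats::median)
  per_peptide <- data.frame(peptide = names(per),
                            median_foldchange = as.numeric(per),
                            n = as.integer(table(m$peptide)[names(per)]),
                            stringsAsFactors = FALSE, row.names = NULL)
  list(per_peptide = per_peptide,
       median_foldchange = stats::median(per_peptide$median_foldchange))
}

#' Retention-time agreement QC
#'
#' Per peptide, the median absolute retention-time difference between the
#' light and heavy channels matched by run (co-elution check), and per
#' (peptide, platform), the classic CV of light-channel retention times
#' across runs (stability check). Retention times are in minutes.
#'
#' @param table A `quant_table` with `rt` present for both channels.
#' @return A list with `per_peptide_diff` (`peptide`,
#'   `median_abs_rt_diff_min`), `per_peptide_platform_cv` (`peptide`,
#'   `platform_id`, `rt_cv_pct`) and `summary` (median difference and
#'   median CV).
#' @export
rt_agreement <- function(table) {
  df <- as.data.frame(table)
  if (!"rt" %in% names(df)) stop("rt column required")
  df$peptide <- precursor_id(df$modified_seq, df$charge)
  light <- df[df$channel == "L" & !is.na(df$rt), , drop = FALSE]
  heavy <- df[df$channel == "H" & !is.na(df$rt),
              c("run_id", "peptide", "rt")]
  names(heavy)[3L] <- "rt_h"
  m <- merge(light[, c("run_id", "peptide", "rt")], heavy,
             by = c("run_id", "peptide"))
  dmed <- tapply(abs(m$rt - m$rt_h), m$peptide, stats::median)
  per_peptide_diff <- data.frame(peptide = names(dmed),
                                 median_abs_rt_diff_min = as.numeric(dmed),
                                 stringsAsFactors = FALSE, row.names = NULL)
  key <- paste(light$peptide, light$platform_id, sep = "\r")
  cvs <- tapply(light$rt, key, cv, method = "classic")
  parts <- strsplit(names(cvs), "\r", fixed = TRUE)
  per_pp <- data.frame(
    peptide = vapply(parts, `[`, character(1), 1L),
    platform_id = vapply(parts, `[`, character(1), 2L),
    rt_cv_pct = as.numeric(cvs), stringsAsFactors = FALSE, row.names = NULL)
  list(per_peptide_diff = per_peptide_diff,
       per_peptide_platform_cv = per_pp,
       summary = list(
         median_rt_diff_min = stats::median(per_peptide_diff$median_abs_rt_diff_min),
         median_rt_cv_pct = stats::median(per_pp$rt_cv_pct, na.rm = TRUE)))
}
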