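# Cross-matrix / cross-platform statistical evaluation battery: Kendall
# trend tests with BH adjustment, paired Wilcoxon tests, intraclass
# correlation, KNN imputation, random-effects variance partitioning,
# Bland-Altman agreement, composite-dataset construction, per-group
# regression and PCA scores.

tie_counts <- function(x) {
  t <- table(x)
  t[t > 1L]
}

#' Kendall tau trend test against an ordinal grouping
#'
#' Computes Kendall's tau-b with tie correction between values and ordinal
#' group ranks, and a two-sided p-value from the tie-corrected normal
#' approximation with continuity correction (the convention of standard
#' trend-test implementations), used for all sample sizes.
#'
#' @param values Numeric values (e.g. normalized peptide quantities);
#'   missing values are dropped pairwise with their groups.
#' @param groups Ordinal group ranks (numeric) or an ordered factor.
#' @return A list with `tau`, `p`, `S` (concordant minus discordant
#'   pairs), `var_s` and `n`.
#' @export
kendall_trend <- function(values, groups) {
  if (is.factor(groups)) groups <- as.numeric(groups)
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]
  g <- groups[ok]
  n <- length(v)
  if (n < 3L || length(unique(g)) < 2L) {
    return(list(tau = NA_real_, p = NA_real_, S = NA_real_,
                var_s = NA_real_, n = n))
  }
  if (length(unique(v)) < 2L) {
    return(list(tau = NA_real_, p = NA_real_, S = NA_real_,
                var_s = NA_real_, n = n))
  }
  dv <- sign(outer(v, v, "-"))
  dg <- sign(outer(g, g, "-"))
  S <- sum(dv[lower.tri(dv)] * dg[lower.tri(dg)])
  t_v <- as.numeric(tie_counts(v))
  t_g <- as.numeric(tie_counts(g))
  n0 <- n * (n - 1) / 2
  n1 <- sum(t_v * (t_v - 1) / 2)
  n2 <- sum(t_g * (t_g - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(t_v * (t_v - 1) * (2 * t_v + 5)) -
              sum(t_g * (t_g - 1) * (2 * t_g + 5))) / 18
  if (n > 2L) {
    var_s <- var_s +
      sum(t_v * (t_v - 1) * (t_v - 2)) * sum(t_g * (t_g - 1) * (t_g - 2)) /
        (9 * n * (n - 1) * (n - 2)) +
      sum(t_v * (t_v - 1)) * sum(t_g * (t_g - 1)) / (2 * n * (n - 1))
  }
  z <- if (S == 0 || var_s <= 0) 0 else (S - sign(S)) / sqrt(var_s)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(tau = tau, p = p, S = S, var_s = var_s, n = n)
}

#' Trend test over a peptide matrix
#'
#' Applies [kendall_trend()] to each row of a peptides-by-samples matrix
#' against an ordinal severity grouping, with Benjamini-Hochberg
#' adjustment over the peptides of this dataset (adjustment is performed
#' within one dataset, matching per-platform correction).
#'
#' @param mat Peptides-by-samples numeric matrix.
#' @param groups Ordinal group per sample (column).
#' @return A data frame: `peptide`, `tau`, `p`, `p_adjust`.
#' @export
trend_test <- function(mat, groups) {
  res <- apply(mat, 1L, function(v) {
    k <- kendall_trend(v, groups)
    c(k$tau, k$p)
  })
  out <- data.frame(peptide = rownames(mat) %||% seq_len(nrow(mat)),
                    tau = res[1L, ], p = res[2L, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adjust <- NA_real_
  ok <- !is.na(out$p)
  out$p_adjust[ok] <- bh_adjust(out$p[ok])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1 and order-preserving.
#'
#' @param pvalues Raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired observations; zero differences
#' are dropped, the exact distribution is used for n <= 25 untied
#' differences and the normal approximation with continuity correction
#' otherwise. With no nonzero difference the test is undefined and `NA`
#' is returned.
#'
#' @param a,b Paired numeric vectors (same samples).
#' @param exact_n Largest number of nonzero differences for which the
#'   exact null distribution is used.
#' @return Two-sided p-value, or `NA` when undefined.
#' @export
paired_wilcoxon <- function(a, b, exact_n = 25L) {
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  if (length(d) == 0L) return(NA_real_)
  use_exact <- length(d) <= exact_n && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(d, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Intraclass correlation coefficient
#'
#' From the two-way ANOVA decomposition of a samples-by-raters matrix
#' (raters are platforms): `ICC(3,k) = (MS_rows - MS_err) / MS_rows`
#' (two-way mixed effects, average measures, consistency) and
#' `ICC(2,1) = (MS_rows - MS_err) / (MS_rows + (k-1) MS_err +
#' k (MS_cols - MS_err) / n)` (two-way random, single measures, absolute
#' agreement). Rows with missing values are removed listwise.
#'
#' @param mat Samples-by-raters numeric matrix.
#' @param model `"ICC3k"` or `"ICC21"`.
#' @return The ICC value, or `NA` with fewer than 2 complete rows.
#' @export
icc <- function(mat, model = c("ICC3k", "ICC21")) {
  model <- match.arg(model)
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2L || k < 2L) return(NA_real_)
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ms_rows <- k * sum((row_m - grand)^2) / (n - 1)
  ms_cols <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- mat - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand
  ms_err <- sum(resid^2) / ((n - 1) * (k - 1))
  if (model == "ICC3k") {
    if (ms_rows == 0) return(NA_real_)
    (ms_rows - ms_err) / ms_rows
  } else {
    denom <- ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n
    if (denom == 0) return(NA_real_)
    (ms_rows - ms_err) / denom
  }
}

#' K-nearest-neighbor imputation of a peptide matrix
#'
#' Imputes missing entries of a peptides-by-samples matrix treating
#' samples as observations (the matrix is conceptually transposed, imputed
#' and transposed back): a missing value of peptide p in sample s is the
#' unweighted mean of p's values in the k samples nearest to s by
#' Euclidean distance over co-observed peptides, scaled by the number of
#' co-observed coordinates. When fewer than k candidate neighbors carry
#' the peptide, all available ones are used with a warning; with no
#' candidate at all the peptide's row mean is used.
#'
#' @param mat Peptides-by-samples numeric matrix with `NA` for missing;
#'   each row must have at least one observed value.
#' @param k Number of neighbors.
#' @return The completed matrix.
#' @export
knn_impute <- function(mat, k = 10L) {
  if (k <= 0L) stop("k must be positive")
  mat <- as.matrix(mat)
  if (any(rowSums(!is.na(mat)) == 0L)) {
    stop("every peptide (row) needs at least one observed value")
  }
  if (!anyNA(mat)) return(mat)
  n_s <- ncol(mat)
  # pairwise sample distances over co-observed peptides
  dist_s <- matrix(NA_real_, n_s, n_s)
  for (i in seq_len(n_s - 1L)) {
    for (j in seq(i + 1L, n_s)) {
      co <- !is.na(mat[, i]) & !is.na(mat[, j])
      if (any(co)) {
        dist_s[i, j] <- dist_s[j, i] <-
          sqrt(mean((mat[co, i] - mat[co, j])^2))
      }
    }
  }
  out <- mat
  warned <- FALSE
  for (s in which(colSums(is.na(mat)) > 0L)) {
    for (p in which(is.na(mat[, s]))) {
      cand <- which(!is.na(mat[p, ]) & !is.na(dist_s[s, ]))
      if (length(cand) == 0L) {
        out[p, s] <- mean(mat[p, ], na.rm = TRUE)
        next
      }
      if (length(cand) < k && !warned) {
        warning("fewer than k neighbors available; using all available")
        warned <- TRUE
      }
      nb <- cand[order(dist_s[s, cand])][seq_len(min(k, length(cand)))]
      out[p, s] <- mean(mat[p, nb])
    }
  }
  out
}

#' Variance partitioning with random platform and severity effects
#'
#' Per peptide, fits the random-intercept model
#' `value ~ (1 | platform) + (1 | severity)` by REML and reports the
#' fraction of variance attributable to each component and to the
#' residual. The matrix must be complete (impute first, see
#' [knn_impute()]). Peptides whose fit fails are returned with missing
#' fractions and flagged.
#'
#' @param mat Peptides-by-samples complete numeric matrix.
#' @param design A data frame with one row per sample (column of `mat`),
#'   columns `platform` and `severity`.
#' @return A data frame: `peptide`, `frac_platform`, `frac_severity`,
#'   `frac_residual`, `converged`. Fractions sum to 1.
#' @export
variance_partition <- function(mat, design) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete; impute first")
  stopifnot(nrow(design) == ncol(mat))
  if (length(unique(design$platform)) < 2L ||
      length(unique(design$severity)) < 2L) {
    stop("need at least 2 levels of platform and severity")
  }
  d0 <- data.frame(platform = factor(design$platform),
                   severity = factor(design$severity))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    d0$value <- mat[i, ]
    fit <- tryCatch(
      suppressMessages(lme4::lmer(value ~ (1 | platform) + (1 | severity),
                                  data = d0, REML = TRUE, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(frac_platform = NA_real_, frac_severity = NA_real_,
                        frac_residual = NA_real_, converged = FALSE))
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc$vcov, vc$grp)
    total <- sum(v)
    data.frame(frac_platform = unname(v["platform"]) / total,
               frac_severity = unname(v["severity"]) / total,
               frac_residual = unname(v["Residual"]) / total,
               converged = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(peptide = rownames(mat) %||% seq_len(nrow(mat)),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements, the bias is the mean difference, the limits
#' of agreement (LoA) are `bias +/- 1.96 * SD` of the differences, and
#' 95% confidence intervals for the bias and each LoA come from the
#' Student t distribution with n - 1 degrees of freedom, with standard
#' errors `SD/sqrt(n)` for the bias and
#' `SD * sqrt(1/n + 1.96^2 / (2 (n - 1)))` for the limits. Non-finite
#' pairs are removed.
#'
#' @param x,y Paired numeric vectors (e.g. the same peptide's ratios in
#'   two datasets).
#' @param conf Confidence level for the intervals.
#' @return A list with `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `ci_bias`, `ci_loa_low`, `ci_loa_high`.
#' @export
bland_altman <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2L) {
    return(list(n = n, bias = NA_real_, sd_diff = NA_real_,
                loa_low = NA_real_, loa_high = NA_real_,
                ci_bias = c(NA_real_, NA_real_),
                ci_loa_low = c(NA_real_, NA_real_),
                ci_loa_high = c(NA_real_, NA_real_)))
  }
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- c(bias - 1.96 * s, bias + 1.96 * s)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  list(n = n, bias = bias, sd_diff = s,
       loa_low = loa[1L], loa_high = loa[2L],
       ci_bias = bias + c(-1, 1) * tq * se_bias,
       ci_loa_low = loa[1L] + c(-1, 1) * tq * se_loa,
       ci_loa_high = loa[2L] + c(-1, 1) * tq * se_loa)
}

#' Build a composite cross-platform dataset
#'
#' For each sample of the source cohort, draws one non-holdout platform
#' uniformly at random (seeded) among the platforms carrying that sample,
#' and takes the sample's normalized values from it. The sample set —
#' hence the severity distribution — is identical to the source cohort;
#' holding out a platform avoids data leakage when comparing the
#' composite against it.
#'
#' @param tables Named list of normalized tables (one per platform) with
#'   columns `sample_id`, `peptide`, `group` and the value column.
#' @param holdout Platform name excluded from the draw (may be `NULL`).
#' @param seed Integer seed for the platform draws.
#' @return One normalized table with an added `source_platform` column.
#' @export
composite_dataset <- function(tables, holdout = NULL, seed = 1L) {
  use <- setdiff(names(tables), holdout)
  if (length(use) == 0L) stop("no non-holdout platform available")
  # the source cohort is defined by all platforms, holdout included
  samples <- sort(unique(unlist(lapply(tables, function(t) t$sample_id))))
  has <- vapply(use, function(p) {
    s <- unique(tables[[p]]$sample_id)
    samples %in% s
  }, logical(length(samples)))
  has <- matrix(has, nrow = length(samples),
                dimnames = list(samples, use))
  orphan <- samples[rowSums(has) == 0L]
  if (length(orphan) > 0L) {
    stop("sample(s) absent from all non-holdout platforms: ",
         paste(orphan, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  picks <- vapply(seq_along(samples), function(i) {
    avail <- use[has[i, ]]
    if (length(avail) == 1L) avail else sample(avail, 1L)
  }, character(1))
  rows <- lapply(seq_along(samples), function(i) {
    t <- tables[[picks[i]]]
    sub <- t[t$sample_id == samples[i], , drop = FALSE]
    sub$source_platform <- picks[i]
    sub
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group linear regression between two methods
#'
#' Ordinary least squares of `y` on `x` within each group; reports the
#' slope and coefficient of determination per group. Cells with fewer
#' than 3 complete pairs or zero x-variance are undefined.
#'
#' @param x,y Paired quantities from two methods.
#' @param groups Group label per pair (e.g. severity group).
#' @return A data frame: `group`, `n`, `slope`, `r2`.
#' @export
group_regression <- function(x, y, groups) {
  rows <- lapply(split(seq_along(x), groups), function(idx) {
    xi <- x[idx]
    yi <- y[idx]
    ok <- is.finite(xi) & is.finite(yi)
    xi <- xi[ok]
    yi <- yi[ok]
    if (length(xi) < 3L || stats::var(xi) == 0) {
      return(data.frame(n = length(xi), slope = NA_real_, r2 = NA_real_))
    }
    fit <- stats::lm(yi ~ xi)
    data.frame(n = length(xi), slope = unname(stats::coef(fit)[2L]),
               r2 = suppressWarnings(summary(fit)$r.squared))
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(group = names(rows), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' PCA scores and explained variance
#'
#' Singular-value decomposition of the (centered, optionally scaled)
#' samples-by-peptides matrix; the matrix must be complete (impute
#' first).
#'
#' @param mat Samples-by-peptides complete numeric matrix.
#' @param center,scale Centering/scaling flags passed to the
#'   decomposition.
#' @return A list with `scores` (samples by components) and `explained`
#'   (variance fractions, non-increasing, summing to at most 1).
#' @export
pca_scores <- function(mat, center = TRUE, scale = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 samples")
  if (anyNA(mat)) stop("matrix must be complete; impute first")
  pr <- stats::prcomp(mat, center = center, scale. = scale)
  list(scores = pr$x, explained = pr$sdev^2 / sum(pr$sdev^2))
}
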