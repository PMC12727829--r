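test_that("Kendall trend statistics match perfect and reversed orderings", {
  k <- kendall_trend(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(k$tau, 1)
  k2 <- kendall_trend(c(4, 3, 2, 1), c(1, 2, 3, 4))
  expect_equal(k2$tau, -1)
  # degenerate inputs are undefined
  expect_true(is.na(kendall_trend(c(1, 1, 1), c(1, 2, 3))$tau))
  expect_true(is.na(kendall_trend(c(1, 2, 3), c(2, 2, 2))$tau))
})

test_that("Kendall tau-b equals brute-force pair counting with ties", {
  withr::local_seed(21)
  for (trial in 1:30) {
    n <- 6
    v <- sample(1:4, n, replace = TRUE) + stats::rnorm(n, 0, 0.01)
    if (trial %% 2 == 0) v <- sample(1:3, n, replace = TRUE)  # value ties
    g <- sample(1:3, n, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) < 2) next
    k <- kendall_trend(v, g)
    conc <- disc <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- sign(v[j] - v[i]) * sign(g[j] - g[i])
        if (s > 0) conc <- conc + 1
        if (s < 0) disc <- disc + 1
      }
    }
    t_v <- table(v)
    t_g <- table(g)
    n0 <- n * (n - 1) / 2
    n1 <- sum(t_v * (t_v - 1) / 2)
    n2 <- sum(t_g * (t_g - 1) / 2)
    expect_equal(k$S, conc - disc)
    expect_equal(k$tau, (conc - disc) / sqrt((n0 - n1) * (n0 - n2)),
                 tolerance = 1e-12)
    # cross-check tau-b against the base implementation
    expect_equal(k$tau, unname(stats::cor(v, g, method = "kendall")),
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")

  withr::local_seed(8)
  for (trial in 1:25) {
    n <- sample(1:6, 1)
    p <- round(stats::runif(n, 0.001, 1), 3)
    got <- bh_adjust(p)
    # brute-force step-up: sort, p_(i) * n / i, cumulative min from the top
    ord <- order(p)
    padj_sorted <- p[ord] * n / seq_len(n)
    for (i in rev(seq_len(n - 1))) {
      padj_sorted[i] <- min(padj_sorted[i], padj_sorted[i + 1])
    }
    oracle <- numeric(n)
    oracle[ord] <- pmin(padj_sorted, 1)
    expect_equal(got, oracle, tolerance = 1e-12)
    # order invariance and dominance
    perm <- sample(n)
    expect_equal(bh_adjust(p[perm]), got[perm], tolerance = 1e-12)
    expect_true(all(got >= p - 1e-15 & got <= 1))
  }
})

test_that("paired Wilcoxon matches the exact signed-rank null", {
  expect_true(is.na(paired_wilcoxon(1:5, 1:5)))
  # six positive differences, no ties: two-sided exact p = 2/2^6
  expect_equal(paired_wilcoxon(c(2, 3, 4, 5, 6, 7) + 0.1 * 1:6,
                               c(1, 2, 3, 4, 5, 6)),
               0.03125)
  # enumeration oracle over all sign assignments for n <= 10
  withr::local_seed(14)
  for (trial in 1:10) {
    n <- sample(4:10, 1)
    d <- round(stats::rnorm(n, 0.3, 1), 4)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    m <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    v_all <- signs %*% r
    p_oracle <- mean(abs(v_all - m * (m + 1) / 4) >=
                       abs(v_obs - m * (m + 1) / 4) - 1e-12)
    expect_equal(paired_wilcoxon(d, rep(0, length(d))), p_oracle,
                 tolerance = 1e-9)
  }
})

test_that("ICC models agree with the two-way ANOVA decomposition", {
  # identical columns: perfect reliability under both models
  m <- cbind(1:6, 1:6, 1:6)
  expect_equal(icc(m, "ICC3k"), 1)
  expect_equal(icc(m, "ICC21"), 1)

  # 4x2 toy matrix against hand-computed mean squares
  m2 <- matrix(c(1, 2, 3, 4,
                 2, 4, 2, 6), ncol = 2)
  n <- 4; k <- 2
  grand <- mean(m2)
  ms_rows <- k * sum((rowMeans(m2) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(m2) - grand)^2) / (k - 1)
  ss_tot <- sum((m2 - grand)^2)
  ms_err <- (ss_tot - (n - 1) * ms_rows / k * k - (k - 1) * ms_cols / n * n) /
    ((n - 1) * (k - 1))
  expect_equal(icc(m2, "ICC3k"), (ms_rows - ms_err) / ms_rows,
               tolerance = 1e-12)
  expect_equal(icc(m2, "ICC21"),
               (ms_rows - ms_err) /
                 (ms_rows + (k - 1) * ms_err + k * (ms_cols - ms_err) / n),
               tolerance = 1e-12)

  # independent noise columns: ICC near zero at large n
  withr::local_seed(2)
  noise <- cbind(stats::rnorm(4000), stats::rnorm(4000))
  expect_lt(abs(icc(noise, "ICC3k")), 0.08)

  # listwise deletion leaves too few rows -> undefined
  m3 <- cbind(c(1, NA), c(2, 3))
  expect_true(is.na(icc(m3, "ICC3k")))
})

test_that("KNN imputation averages the nearest samples and handles edge cases", {
  m <- matrix(1:12, nrow = 3)
  expect_equal(knn_impute(m), m)  # no missing: identity

  # identical columns: missing entry restored to the shared constant
  m2 <- matrix(rep(c(1, 5, 9), 4), nrow = 3)
  m2[2, 3] <- NA
  expect_warning(got <- knn_impute(m2, k = 10), "fewer than k")
  expect_equal(got[2, 3], 5)

  # 5x4 case against brute-force neighbor averaging with k = 2
  withr::local_seed(6)
  m3 <- matrix(stats::rnorm(20), nrow = 5)
  m3[2, 1] <- NA
  got3 <- knn_impute(m3, k = 2)
  d <- vapply(2:4, function(j) {
    co <- !is.na(m3[, 1]) & !is.na(m3[, j])
    sqrt(mean((m3[co, 1] - m3[co, j])^2))
  }, numeric(1))
  nb <- (2:4)[order(d)][1:2]
  expect_equal(got3[2, 1], mean(m3[2, nb]))
  expect_error(knn_impute(m3, k = 0), "positive")
  m4 <- m3
  m4[1, ] <- NA
  expect_error(knn_impute(m4), "at least one observed")
})

test_that("variance partitioning attributes planted variance correctly", {
  withr::local_seed(31)
  n_s <- 48
  design <- data.frame(platform = rep(c("a", "b", "c"), length.out = n_s),
                       severity = rep(1:4, each = n_s / 4))
  # pure platform offsets, tiny noise: platform fraction near 1
  off <- c(a = 0, b = 5, c = 10)
  m1 <- matrix(rep(off[design$platform], each = 4), nrow = 4, byrow = FALSE) +
    matrix(stats::rnorm(4 * n_s, 0, 0.01), nrow = 4)
  vp1 <- variance_partition(m1, design)
  expect_true(all(vp1$frac_platform > 0.95))
  # pure i.i.d. noise: both factor fractions near zero
  m2 <- matrix(stats::rnorm(6 * n_s), nrow = 6)
  vp2 <- variance_partition(m2, design)
  expect_lt(stats::median(vp2$frac_platform), 0.1)
  expect_lt(stats::median(vp2$frac_severity), 0.1)
  # fractions always sum to one
  sums <- rowSums(vp1[, c("frac_platform", "frac_severity", "frac_residual")])
  expect_equal(sums, rep(1, 4), tolerance = 1e-9)
  expect_error(variance_partition(cbind(1, NA), design[1:2, ]), "complete")
})

test_that("Bland-Altman agrees with the closed-form t oracle", {
  z <- bland_altman(1:10, 1:10)
  expect_equal(z$bias, 0)
  expect_equal(z$sd_diff, 0)
  b <- bland_altman(2:6, 2:6 - 0.5)
  expect_equal(b$bias, 0.5)
  expect_equal(c(b$loa_low, b$loa_high), c(0.5, 0.5))

  withr::local_seed(19)
  x <- stats::rnorm(10, 1, 0.5)
  y <- x + stats::rnorm(10, 0.2, 0.3)
  ba <- bland_altman(x, y)
  d <- x - y
  n <- 10
  s <- sqrt(sum((d - mean(d))^2) / (n - 1))
  tq <- stats::qt(0.975, n - 1)
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$ci_bias, mean(d) + c(-1, 1) * tq * s / sqrt(n),
               tolerance = 1e-12)
  se_loa <- s * sqrt(1 / n + 1.96^2 / (2 * (n - 1)))
  expect_equal(ba$ci_loa_low,
               mean(d) - 1.96 * s + c(-1, 1) * tq * se_loa,
               tolerance = 1e-12)
  # a dataset against itself has exactly zero bias
  expect_identical(bland_altman(x, x)$bias, 0)
})

test_that("composite datasets preserve samples, severity and determinism", {
  mk <- function(pf, samples, val) {
    data.frame(sample_id = samples, peptide = "pepA/2",
               platform_id = pf,
               group = rep(c("healthy", "mild", "severe", "critical"),
                           length.out = length(samples)),
               ratio = val, stringsAsFactors = FALSE)
  }
  samples <- sprintf("S%02d", 1:12)
  tabs <- list(p1 = mk("p1", samples, 1), p2 = mk("p2", samples, 2),
               p3 = mk("p3", samples, 3))
  # one non-holdout platform: composite equals that table
  comp1 <- composite_dataset(tabs[c("p1", "p3")], holdout = "p3", seed = 5)
  expect_equal(comp1$ratio, rep(1, 12))
  # severity histogram identical to the source cohort
  comp <- composite_dataset(tabs, holdout = "p3", seed = 5)
  expect_equal(table(comp$group), table(tabs$p1$group))
  expect_setequal(comp$sample_id, samples)
  expect_true(all(comp$source_platform %in% c("p1", "p2")))
  # same seed reproduces; different seed changes assignments
  comp_b <- composite_dataset(tabs, holdout = "p3", seed = 5)
  expect_identical(comp, comp_b)
  different <- any(vapply(1:10, function(s) {
    !identical(composite_dataset(tabs, holdout = "p3", seed = s)$source_platform,
               comp$source_platform)
  }, logical(1)))
  expect_true(different)
  # missing sample on all non-holdout platforms errors with its name
  tabs2 <- tabs
  tabs2$p1 <- tabs2$p1[-1, ]
  tabs2$p2 <- tabs2$p2[-1, ]
  expect_error(composite_dataset(tabs2, holdout = "p3"), "S01")
})

test_that("per-group regression matches the normal-equations oracle", {
  g <- rep(c("a", "b"), each = 5)
  x <- c(1:5, 1:5)
  y <- c(1:5, 2 * (1:5) + 3)
  gr <- group_regression(x, y, g)
  expect_equal(gr$slope, c(1, 2))
  expect_equal(gr$r2, c(1, 1))

  withr::local_seed(23)
  x2 <- stats::rnorm(5)
  y2 <- 1.3 * x2 + stats::rnorm(5, 0, 0.2)
  gr2 <- group_regression(x2, y2, rep("g", 5))
  sxy <- sum((x2 - mean(x2)) * (y2 - mean(y2)))
  sxx <- sum((x2 - mean(x2))^2)
  expect_equal(gr2$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(gr2$r2, (sxy / sxx)^2 * sxx / sum((y2 - mean(y2))^2),
               tolerance = 1e-12)
  # undefined cells
  expect_true(is.na(group_regression(rep(1, 4), 1:4, rep("g", 4))$slope))
})

test_that("PCA scores follow the eigen-decomposition on a toy matrix", {
  # rank-1 data: first component explains everything
  m <- outer(c(1, 2, 3, 4), c(2, 1, 0.5))
  p <- pca_scores(m)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))

  withr::local_seed(29)
  m2 <- matrix(stats::rnorm(12), nrow = 4)
  p2 <- pca_scores(m2)
  cc <- scale(m2, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cc) / (nrow(m2) - 1))
  expect_equal(p2$explained, ev$values / sum(ev$values), tolerance = 1e-9)
  expect_equal(abs(as.numeric(p2$scores[, 1])),
               abs(as.numeric(cc %*% ev$vectors[, 1])), tolerance = 1e-9)
  expect_error(pca_scores(m2[1, , drop = FALSE]), "2 samples")
})

test_that("null Kendall trend tests reject at the nominal 5% level", {
  withr::local_seed(2027)
  n_pep <- 2000
  n <- 40
  groups <- rep(1:4, each = n / 4)
  p <- vapply(seq_len(n_pep), function(i) {
    kendall_trend(stats::rnorm(n), groups)$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  mc3 <- 3 * sqrt(0.05 * 0.95 / n_pep)
  expect_lt(abs(rate - 0.05), mc3 + 0.002)
})

test_that("ratio normalization beats median normalization on platform variance", {
  sim <- simulate_cohort(seed = 90L)
  pool_runs <- unique(sim$quant$run_id[sim$quant$group == "pool"])
  norm <- normalize_table(sim$quant, pool_runs = pool_runs, method = "both")
  samp <- norm[norm$group != "pool", ]
  design <- NULL
  frac_platform <- function(value) {
    wide <- stats::reshape(
      samp[, c("peptide", "run_id", value)],
      idvar = "peptide", timevar = "run_id", direction = "wide")
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide$peptide
    runs <- sub(paste0("^", value, "\\."), "", colnames(mat))
    meta <- samp[match(runs, samp$run_id), c("platform_id", "group")]
    d <- data.frame(platform = meta$platform_id, severity = meta$group)
    mat <- knn_impute(mat, k = 10)
    vp <- variance_partition(mat, d)
    stats::median(vp$frac_platform, na.rm = TRUE)
  }
  expect_lt(frac_platform("ratio"), frac_platform("norm_light"))
})
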