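# helper: two-platform cohort-style table with pool runs built in code
two_platform_table <- function() {
  rows <- list()
  for (pf in c("p1", "p2")) {
    for (smp in c("pool_a", "pool_b", "s1", "s2", "s3")) {
      run <- paste(pf, smp, sep = "_")
      for (i in 1:3) {
        base <- c(10, 40, 160)[i] * ifelse(pf == "p2", 5, 1)
        rows[[length(rows) + 1L]] <- quant_row(
          run = run, platform = pf, sample = smp,
          group = ifelse(grepl("pool", smp), "pool", "patient"),
          seq = toy_seq(i), intensity = base, channel = "L")
        rows[[length(rows) + 1L]] <- quant_row(
          run = run, platform = pf, sample = smp,
          group = ifelse(grepl("pool", smp), "pool", "patient"),
          seq = toy_seq(i), intensity = base / 2, channel = "H")
      }
    }
  }
  as_quant_table(do.call(rbind, rows))
}

test_that("completeness filter is strictly greater than the threshold", {
  rows <- list()
  for (j in 1:12) {
    for (i in 1:3) {
      detected <- (i == 1 && j <= 9) || (i == 2 && j <= 8) || i == 3
      if (detected) {
        rows[[length(rows) + 1L]] <- quant_row(
          run = paste0("r", j), sample = paste0("smp", j),
          seq = toy_seq(i), intensity = 10)
      }
    }
  }
  qt <- as_quant_table(do.call(rbind, rows))
  cf <- completeness_filter(qt)
  expect_true(cf$retained[cf$peptide == paste0(toy_seq(1), "/2")])   # 9/12
  expect_false(cf$retained[cf$peptide == paste0(toy_seq(2), "/2")])  # 8/12 exact
  expect_true(cf$retained[cf$peptide == paste0(toy_seq(3), "/2")])   # 12/12
})

test_that("median normalization uses one pool-median factor per platform", {
  qt <- two_platform_table()
  pool_runs <- unique(qt$run_id[qt$group == "pool"])
  nl <- median_normalize(qt, pool_runs)
  f <- attr(nl, "median_factors")
  # oracle: brute-force median of pool light intensities per platform
  light <- as.data.frame(qt)
  light <- light[light$channel == "L" & light$run_id %in% pool_runs, ]
  for (pf in c("p1", "p2")) {
    expect_equal(unname(f[pf]),
                 stats::median(light$intensity[light$platform_id == pf]))
  }
  expect_equal(f[["p2"]], 5 * f[["p1"]])
  # sample value 5 against factor 10 gives 0.5
  expect_equal(stats::median(light$intensity[light$platform_id == "p1"]), 40)
  one <- nl$norm_light[nl$platform_id == "p1" &
                         nl$peptide == paste0(toy_seq(1), "/2")][1]
  expect_equal(one, 10 / 40)
  # a platform-global rescale cancels exactly
  scaled <- as.data.frame(qt)
  scaled$intensity <- scaled$intensity * 7
  nl2 <- median_normalize(as_quant_table(scaled), pool_runs)
  expect_equal(nl2$norm_light, nl$norm_light, tolerance = 1e-12)
  # all-missing pool errors
  expect_error(median_normalize(qt, "no_such_run"), "pool")
})

test_that("SIL ratios divide light by heavy and respect missingness", {
  df <- rbind(
    quant_row(run = "r1", channel = "L", intensity = 4),
    quant_row(run = "r1", channel = "H", intensity = 2),
    quant_row(run = "r2", channel = "L", intensity = 4),
    quant_row(run = "r1", seq = "TTEAVFDGR", channel = "L", intensity = 9),
    quant_row(run = "r1", seq = "TTEAVFDGR", channel = "H", intensity = NA)
  )
  rt <- ratio_normalize(as_quant_table(df))
  expect_equal(rt$ratio[rt$run_id == "r1" &
                          rt$peptide == "SPELQAEAK/2"], 2)
  expect_true(is.na(rt$ratio[rt$run_id == "r2"]))          # SIS missing
  expect_true(is.na(rt$ratio[rt$peptide == "TTEAVFDGR/2"])) # SIS NA

  # exact invariance under per-run channel-shared scaling
  qt <- two_platform_table()
  base <- ratio_normalize(qt)
  scaled <- as.data.frame(qt)
  run_fac <- stats::setNames(seq_along(unique(scaled$run_id)) * 3.7,
                             unique(scaled$run_id))
  scaled$intensity <- scaled$intensity * run_fac[scaled$run_id]
  rt2 <- ratio_normalize(as_quant_table(scaled))
  expect_identical(rt2$ratio, base$ratio)
})

test_that("robust and classic CVs follow their formulas", {
  expect_equal(cv(c(5, 5, 5, 5), "robust"), 0)
  expect_equal(cv(c(5, 5, 5, 5), "classic"), 0)
  # scaled MAD: 1.4826 * 1 / 2 * 100
  expect_equal(cv(c(1, 2, 3), "robust"), 74.13)
  expect_equal(cv(c(8, 12), "classic"), 100 * sqrt(8) / 10,
               tolerance = 1e-12)
  expect_true(is.na(cv(c(3), "classic")))
  expect_equal(cv(c(1, 2, 3), "robust", mad_constant = 1), 50)
})

test_that("robust CV equals a brute-force MAD oracle on short inputs", {
  withr::local_seed(9)
  for (trial in 1:30) {
    n <- sample(2:7, 1)
    v <- round(stats::rlnorm(n, 2, 0.6), 2)
    med <- sort(v)[ceiling(n / 2)]
    if (n %% 2 == 0) med <- mean(sort(v)[n / 2 + c(0, 1)])
    absdev <- abs(v - med)
    mad_raw <- sort(absdev)[ceiling(n / 2)]
    if (n %% 2 == 0) mad_raw <- mean(sort(absdev)[n / 2 + c(0, 1)])
    expect_equal(cv(v, "robust"), 100 * 1.4826 * mad_raw / med,
                 tolerance = 1e-12)
  }
})

test_that("quantification precursor selection gates on CV then abundance", {
  cand <- data.frame(
    peptide = c("A", "A", "B", "B", "C"),
    precursor = c("A/2", "A/3", "B/2", "B/3", "C/2"),
    protein_group = c("P1", "P1", "P1", "P1", "P2"),
    pool_cv_pct = c(10, 50, 15, 12, 39),
    abundance = c(1000, 2000, 500, 900, 100),
    stringsAsFactors = FALSE)
  sel <- select_quant_precursor(cand)
  # A: charge 3 fails the CV gate despite higher abundance
  expect_equal(sel$precursor[sel$peptide == "A"], "A/2")
  # B: both pass, the more abundant charge 3 wins
  expect_equal(sel$precursor[sel$peptide == "B"], "B/3")
  # C: single candidate at CV 39 (< 40) is selected
  expect_equal(sel$precursor[sel$peptide == "C"], "C/2")
  # a CV of exactly 40 fails the strict gate
  cand$pool_cv_pct[5] <- 40
  expect_warning(sel2 <- select_quant_precursor(cand), "no precursor")
  expect_false("C" %in% sel2$peptide)
  expect_equal(attr(sel2, "unquantifiable"), "C")
  # opposing standard profiles of same-protein peptides are flagged
  profiles <- list("A/2" = 1:8, "B/3" = 8:1, "C/2" = 1:8)
  sel3 <- select_quant_precursor(cand[1:4, ], profiles = profiles)
  expect_true(all(sel3$trend_flag))
})

test_that("fragment profiles keep at most 12 fragments and sum to 100", {
  fr <- data.frame(fragment_id = rep(c("y3", "y5", "y7"), each = 2),
                   run_id = rep(c("r1", "r2"), 3),
                   intensity = c(50, 50, 30, 30, 20, 20),
                   stringsAsFactors = FALSE)
  fd <- fragment_distribution(fr)
  expect_equal(fd$percent, c(50, 30, 20))

  withr::local_seed(4)
  fr14 <- data.frame(fragment_id = rep(sprintf("y%02d", 1:14), each = 3),
                     run_id = rep(c("r1", "r2", "r3"), 14),
                     intensity = stats::rlnorm(42, 3, 1),
                     stringsAsFactors = FALSE)
  fd14 <- fragment_distribution(fr14)
  expect_equal(nrow(fd14), 12L)
  expect_equal(sum(fd14$percent), 100, tolerance = 1e-9)
  # per-run rescaling leaves the profile unchanged
  fr14b <- fr14
  fac <- c(r1 = 2, r2 = 5, r3 = 0.5)
  fr14b$intensity <- fr14b$intensity * fac[fr14b$run_id]
  fd14b <- fragment_distribution(fr14b)
  expect_equal(fd14b$fragment_id, fd14$fragment_id)
  expect_equal(fd14b$percent, fd14$percent, tolerance = 1e-12)
})

test_that("cross-method fold changes behave under scaling and identity", {
  qt <- two_platform_table()
  rt <- ratio_normalize(qt)
  a <- rt[rt$platform_id == "p1", ]
  b <- rt[rt$platform_id == "p2", ]
  same <- cross_method_foldchange(a, a)
  expect_true(all(same$per_peptide$median_foldchange == 1))
  double <- a
  double$ratio <- 2 * double$ratio
  expect_equal(cross_method_foldchange(a, double)$median_foldchange, 0.5)
  # ratio-normalized tables agree across platforms despite the 5x platform
  # scale (both channels carry it)
  expect_equal(cross_method_foldchange(a, b)$median_foldchange, 1)
  expect_error(cross_method_foldchange(a[0, ], b), "overlap")
})

test_that("RT agreement reports co-elution differences and stability CVs", {
  df <- rbind(
    quant_row(run = "r1", intensity = 5, channel = "L", rt = 10),
    quant_row(run = "r1", intensity = 5, channel = "H", rt = 10),
    quant_row(run = "r2", intensity = 5, channel = "L", rt = 10),
    quant_row(run = "r2", intensity = 5, channel = "H", rt = 10)
  )
  ra <- rt_agreement(as_quant_table(df))
  expect_equal(ra$per_peptide_diff$median_abs_rt_diff_min, 0)
  expect_equal(ra$per_peptide_platform_cv$rt_cv_pct, 0)

  # known jitter is recovered within Monte-Carlo error
  withr::local_seed(5)
  n <- 400
  sd_true <- 0.3
  rts <- stats::rnorm(n, mean = 10, sd = sd_true)
  rows <- lapply(seq_len(n), function(j) {
    quant_row(run = paste0("r", j), sample = paste0("s", j),
              intensity = 5, channel = "L", rt = rts[j])
  })
  ra2 <- rt_agreement(as_quant_table(do.call(rbind, rows)))
  expect_equal(ra2$per_peptide_platform_cv$rt_cv_pct, 100 * sd_true / 10,
               tolerance = 0.15)
})

test_that("pool-replicate CVs are lower for ratios than median-normalized values", {
  sim <- simulate_cohort(seed = 77L)
  pool_runs <- unique(sim$quant$run_id[sim$quant$group == "pool"])
  norm <- normalize_table(sim$quant, pool_runs = pool_runs, method = "both")
  pools <- norm[norm$group == "pool", ]
  cv_ratio <- cv_report(pools, value = "ratio")
  cv_nl <- cv_report(pools, value = "norm_light")
  expect_lt(stats::median(cv_ratio$cv_robust_pct, na.rm = TRUE),
            stats::median(cv_nl$cv_robust_pct, na.rm = TRUE))
})
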