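# Seeded synthetic-data generators: multi-study pool series with planted
# "good" and "bad" precursors, a multi-platform clinical cohort with an
# ordinal severity factor and a spiked heavy channel, and replicate
# calibration series. Intensities are log-normal (plasma intensities span
# orders of magnitude) and severity effects act multiplicatively per step.
# Every generator is deterministic given (parameters, seed) and its output
# passes quant-table validation.

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_peptide <- function(n, len_range = c(8L, 15L)) {
  # tryptic-like: canonical residues, no Cys, no N-terminal Gln, ends K/R,
  # no missed-cleavage motifs
  inner <- setdiff(AA_CANONICAL, c("C", "K", "R", "P"))
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1L], len_range[2L]), 1L)
    body <- sample(inner, len - 1L, replace = TRUE)
    if (body[1L] == "Q") body[1L] <- "A"
    paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
  }, character(1))
}

lognormal_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Simulate multi-study pool series
#'
#' Generates study-pool quantification tables for panel selection with
#' planted ground truth: a fraction of "good" precursors (high presence,
#' low CV) and "bad" precursors, half with low presence and half with high
#' CV. Intensities are log-normal around a per-precursor baseline with the
#' planted CV; presence is Bernoulli per run (missing completely at
#' random) or, optionally, intensity-dependent via a logistic detection
#' model. Studies cycle through the four blood matrices. Proteins carry
#' two precursors each (one good, one bad) so the per-protein cap is
#' exercised without hiding planted precursors.
#'
#' @param n_studies Number of study-pool series.
#' @param n_runs_per_study Runs per series (>= 2).
#' @param n_precursors Total precursors.
#' @param frac_good Fraction of planted good precursors.
#' @param good_p_pres,good_cv Presence probability and CV of good
#'   precursors.
#' @param bad_p_pres,bad_cv_low Presence and CV of the low-presence bad
#'   class.
#' @param bad_cv_high CV of the noisy bad class (presence as good).
#' @param missing_mode `"mcar"` or `"intensity"` (logistic in
#'   log-intensity, emulating detection limits).
#' @param seed Integer seed.
#' @return A list with `quant` (a `quant_table`, light channel),
#'   `annotations` and `truth` (per-precursor class, presence, CV).
#' @export
simulate_study_pools <- function(n_studies = 6L, n_runs_per_study = 8L,
                                 n_precursors = 200L, frac_good = 0.5,
                                 good_p_pres = 0.97, good_cv = 0.15,
                                 bad_p_pres = 0.55, bad_cv_low = 0.35,
                                 bad_cv_high = 0.9,
                                 missing_mode = c("mcar", "intensity"),
                                 seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  if (n_runs_per_study < 2L) stop("need at least 2 runs per study")
  if (n_studies < 1L || n_precursors < 2L) stop("invalid parameters")
  with_seed(seed, {
    n_good <- round(frac_good * n_precursors)
    n_bad <- n_precursors - n_good
    cls <- sample(c(rep("good", n_good), rep("bad", n_bad)))
    seqs <- random_peptide(n_precursors)
    while (any(duplicated(seqs))) {
      seqs[duplicated(seqs)] <- random_peptide(sum(duplicated(seqs)))
    }
    p_pres <- ifelse(cls == "good", good_p_pres, bad_p_pres)
    cv_true <- ifelse(cls == "good", good_cv, bad_cv_low)
    noisy <- cls == "bad" & seq_len(n_precursors) %% 2L == 0L
    p_pres[noisy] <- good_p_pres
    cv_true[noisy] <- bad_cv_high
    protein <- paste0("PROT", sprintf("%04d", ceiling(seq_len(n_precursors) / 2)))
    baseline <- stats::rlnorm(n_precursors, meanlog = log(1e5), sdlog = 1.2)
    matrices <- rep(MATRIX_LEVELS[1:4], length.out = n_studies)
    sdlog <- lognormal_sdlog(cv_true)

    rows <- vector("list", n_studies)
    for (s in seq_len(n_studies)) {
      study <- sprintf("study%02d", s)
      run_ids <- sprintf("%s_run%02d", study, seq_len(n_runs_per_study))
      intensity <- matrix(
        stats::rlnorm(n_precursors * n_runs_per_study,
                      meanlog = rep(log(baseline) - sdlog^2 / 2,
                                    n_runs_per_study),
                      sdlog = rep(sdlog, n_runs_per_study)),
        nrow = n_precursors)
      if (missing_mode == "mcar") {
        present <- matrix(
          stats::rbinom(n_precursors * n_runs_per_study, 1L,
                        rep(p_pres, n_runs_per_study)) == 1L,
          nrow = n_precursors)
      } else {
        # logistic detection in log-intensity, centered so the marginal
        # detection probability approximates the planted presence
        center <- log(baseline) - sdlog^2 / 2 +
          stats::qlogis(1 - p_pres) * sdlog
        prob <- stats::plogis((log(intensity) - center) / pmax(sdlog, 0.05))
        present <- matrix(
          stats::rbinom(length(prob), 1L, as.vector(prob)) == 1L,
          nrow = n_precursors)
      }
      idx <- which(present, arr.ind = TRUE)
      rows[[s]] <- data.frame(
        run_id = run_ids[idx[, 2L]],
        study_id = study,
        matrix = matrices[s],
        platform_id = "selection_platform",
        sample_id = run_ids[idx[, 2L]],
        group = "pool",
        protein_group = protein[idx[, 1L]],
        stripped_seq = seqs[idx[, 1L]],
        modified_seq = seqs[idx[, 1L]],
        charge = 2L,
        channel = "L",
        intensity = intensity[idx],
        stringsAsFactors = FALSE)
    }
    quant <- as_quant_table(do.call(rbind, rows))
    annotations <- data.frame(peptide = seqs, protein_group = protein,
                              proteotypic = TRUE, stringsAsFactors = FALSE)
    truth <- data.frame(
      precursor = precursor_id(seqs, 2L), stripped_seq = seqs,
      protein_group = protein, class = cls, p_pres = p_pres,
      cv = cv_true, baseline = baseline, stringsAsFactors = FALSE)
    list(quant = quant, annotations = annotations, truth = truth,
         seed = seed)
  })
}

#' Simulate a multi-platform clinical cohort
#'
#' Generates light- and heavy-channel intensities for a cohort measured on
#' several platforms:
#' `light = baseline * effect^severity_step * response(platform, peptide) *
#' run_factor * noise` and
#' `heavy = spike * response(platform, peptide) * run_factor * noise`,
#' with the per-run factor and the platform-by-peptide response factor
#' shared by both channels, so the true light/heavy ratio is platform-free
#' while raw intensities and the platform-global median both carry
#' peptide-specific platform effects. A planted fraction of peptides
#' responds monotonically (multiplicatively per severity step, half up,
#' half down). Study-pool replicate runs (severity-free) are generated per
#' platform for median factors and pool CVs. The heavy spike is matched to
#' the peptide baseline.
#'
#' @param n_samples Cohort size.
#' @param severity_levels Ordered severity labels.
#' @param platforms Platform identifiers.
#' @param n_peptides Number of peptides.
#' @param frac_effect Fraction of severity-responsive peptides.
#' @param effect_per_step Multiplicative effect per severity step.
#' @param platform_response_sdlog Log-SD of the platform-by-peptide
#'   response factors.
#' @param run_factor_sdlog Log-SD of the per-run factors.
#' @param noise_cv Multiplicative measurement noise CV per channel.
#' @param missing_rate Missing-completely-at-random rate per record.
#' @param n_pool_reps Pool replicate runs per platform.
#' @param rt_jitter_sd_min Retention-time jitter SD in minutes.
#' @param seed Integer seed.
#' @return A list with `quant` (a `quant_table`, both channels, pools
#'   included with group `"pool"`), `design` (sample, group,
#'   severity_rank) and `truth`.
#' @export
simulate_cohort <- function(n_samples = 40L,
                            severity_levels = c("healthy", "mild",
                                                "severe", "critical"),
                            platforms = c("zeno_swath", "diapasef",
                                          "orbitrap_dia"),
                            n_peptides = 40L, frac_effect = 0.4,
                            effect_per_step = 1.4,
                            platform_response_sdlog = 0.7,
                            run_factor_sdlog = 0.25, noise_cv = 0.1,
                            missing_rate = 0.05, n_pool_reps = 5L,
                            rt_jitter_sd_min = 0.05, seed = 1L) {
  if (length(severity_levels) < 2L || length(platforms) < 2L) {
    stop("need at least 2 severity levels and 2 platforms")
  }
  with_seed(seed, {
    seqs <- random_peptide(n_peptides)
    while (any(duplicated(seqs))) {
      seqs[duplicated(seqs)] <- random_peptide(sum(duplicated(seqs)))
    }
    protein <- paste0("CPROT", sprintf("%03d", seq_len(n_peptides)))
    baseline <- stats::rlnorm(n_peptides, meanlog = log(1e5), sdlog = 1)
    spike <- baseline  # concentration-matched standard
    n_eff <- round(frac_effect * n_peptides)
    eff_idx <- sample(seq_len(n_peptides), n_eff)
    direction <- rep(0, n_peptides)
    direction[eff_idx] <- rep(c(1, -1), length.out = n_eff)
    effect <- effect_per_step^direction  # per severity step, multiplicative
    resp <- matrix(stats::rlnorm(length(platforms) * n_peptides,
                                 meanlog = 0, sdlog = platform_response_sdlog),
                   nrow = length(platforms),
                   dimnames = list(platforms, seqs))
    rt_base <- stats::runif(n_peptides, 2, 19)

    sev <- rep(severity_levels, length.out = n_samples)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    design <- data.frame(sample_id = sample_ids, group = sev,
                         severity_rank = match(sev, severity_levels),
                         stringsAsFactors = FALSE)

    sdlog_n <- lognormal_sdlog(noise_cv)
    blocks <- list()
    for (pf in platforms) {
      # cohort samples + pool replicates on this platform
      ids <- c(sample_ids, sprintf("pool_rep%02d", seq_len(n_pool_reps)))
      grps <- c(sev, rep("pool", n_pool_reps))
      steps <- c(design$severity_rank - 1L, rep(0L, n_pool_reps))
      for (i in seq_along(ids)) {
        run <- paste(pf, ids[i], sep = "_")
        runfac <- stats::rlnorm(1L, 0, run_factor_sdlog)
        mu_l <- baseline * effect^steps[i] * resp[pf, ] * runfac
        mu_h <- spike * resp[pf, ] * runfac
        light <- mu_l * stats::rlnorm(n_peptides, -sdlog_n^2 / 2, sdlog_n)
        heavy <- mu_h * stats::rlnorm(n_peptides, -sdlog_n^2 / 2, sdlog_n)
        rt_l <- rt_base + stats::rnorm(n_peptides, 0, rt_jitter_sd_min)
        rt_h <- rt_l + stats::rnorm(n_peptides, 0, 0.002)
        keep_l <- stats::runif(n_peptides) >= missing_rate
        keep_h <- stats::runif(n_peptides) >= missing_rate
        blocks[[length(blocks) + 1L]] <- data.frame(
          run_id = run, study_id = "cohort", matrix = "citrate",
          platform_id = pf, sample_id = ids[i], group = grps[i],
          protein_group = rep(protein, 2L),
          stripped_seq = rep(seqs, 2L), modified_seq = rep(seqs, 2L),
          charge = 2L, channel = rep(c("L", "H"), each = n_peptides),
          intensity = ifelse(c(keep_l, keep_h), c(light, heavy), NA_real_),
          rt = c(rt_l, rt_h), stringsAsFactors = FALSE)
      }
    }
    quant <- as_quant_table(do.call(rbind, blocks))
    truth <- list(
      peptides = data.frame(
        peptide = precursor_id(seqs, 2L), stripped_seq = seqs,
        protein_group = protein, baseline = baseline, spike = spike,
        effect_per_step = effect, direction = direction,
        stringsAsFactors = FALSE),
      platform_response = resp, noise_cv = noise_cv,
      run_factor_sdlog = run_factor_sdlog, missing_rate = missing_rate,
      severity_levels = severity_levels, seed = seed)
    list(quant = quant, design = design, truth = truth)
  })
}

#' Simulate replicate calibration series
#'
#' Responses follow `slope * conc + intercept_r + noise`, with a
#' replicate-specific intercept drawn from Normal(0, intercept_sd) and
#' i.i.d. Normal(0, noise_sd) measurement noise; the default levels form
#' the five-fold serial dilution spanning 0.064 to 1000 pg/ul used for
#' eight-point curves (seven non-zero levels plus an optional blank).
#'
#' @param levels Non-zero calibrant concentrations.
#' @param replicates Number of replicate curves.
#' @param slope,intercept_sd,noise_sd Generating parameters.
#' @param include_blank Add a zero-concentration blank per replicate.
#' @param seed Integer seed.
#' @return A data frame: `replicate`, `conc`, `response`, plus the
#'   per-replicate true intercepts in the `"true_intercepts"` attribute.
#' @export
simulate_calibration <- function(levels = c(0.064, 0.32, 1.6, 8, 40, 200,
                                            1000),
                                 replicates = 3L, slope = 1,
                                 intercept_sd = 0.1, noise_sd = 0.05,
                                 include_blank = FALSE, seed = 1L) {
  if (length(levels) < 2L) stop("need at least 2 levels")
  with_seed(seed, {
    x <- if (include_blank) c(0, levels) else levels
    icpt <- stats::rnorm(replicates, 0, intercept_sd)
    rows <- lapply(seq_len(replicates), function(r) {
      data.frame(replicate = r, conc = x,
                 response = slope * x + icpt[r] +
                   stats::rnorm(length(x), 0, noise_sd))
    })
    out <- do.call(rbind, rows)
    attr(out, "true_intercepts") <- icpt
    out
  })
}
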