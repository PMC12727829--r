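# Precursor ranking and eligibility filtering for internal-standard panel
# selection. The metric weights each precursor by its detection frequency
# over its coefficient of variation within a study-pool series, ranks
# precursors ascending in weight (so the best precursor attains relative
# rank 1), averages relative ranks across studies, and applies presence,
# matrix-coverage, proteotypicity and top-k-per-protein rules, followed by
# physicochemical filters.

#' Per-study precursor presence and CV statistics
#'
#' For each precursor observed in a study-pool series, computes the
#' fraction of runs with a non-missing intensity (`p_pres`) and the
#' coefficient of variation on the linear intensity scale (sample SD over
#' mean of the observed intensities). Precursors never observed in a study
#' are not emitted for that study; a precursor observed in a single run has
#' an undefined CV (`NA`).
#'
#' @param table A `quant_table` covering one or more study-pool series.
#' @param channel Channel to evaluate; the endogenous (light) channel by
#'   default.
#' @return A `precursor_stats` data frame with one row per
#'   (precursor, study): `precursor`, `stripped_seq`, `protein_group`,
#'   `study_id`, `matrix`, `n_runs`, `n_present`, `p_pres`, `mean_intensity`,
#'   `cv`.
#' @export
study_precursor_stats <- function(table, channel = "L") {
  df <- as.data.frame(table)
  df <- df[df$channel == channel, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records for channel ", channel)
  runs_per_study <- tapply(df$run_id, df$study_id,
                           function(x) length(unique(x)))
  if (any(runs_per_study < 2L)) {
    stop("CV undefined: study-pool series with a single run: ",
         paste(names(runs_per_study)[runs_per_study < 2L], collapse = ", "))
  }
  obs <- df[!is.na(df$intensity), , drop = FALSE]
  obs$precursor <- precursor_id(obs$modified_seq, obs$charge)
  key <- paste(obs$study_id, obs$precursor, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    precursor = obs$precursor[first],
    stripped_seq = obs$stripped_seq[first],
    protein_group = obs$protein_group[first],
    study_id = obs$study_id[first],
    matrix = obs$matrix[first],
    stringsAsFactors = FALSE
  )
  out$n_runs <- as.integer(runs_per_study[out$study_id])
  grp <- factor(key, levels = key[first])
  out$n_present <- as.integer(tapply(obs$run_id, grp,
                                     function(x) length(unique(x))))
  out$p_pres <- out$n_present / out$n_runs
  out$mean_intensity <- as.numeric(tapply(obs$intensity, grp, mean))
  sds <- as.numeric(tapply(obs$intensity, grp,
                           function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_))
  out$cv <- sds / out$mean_intensity
  rownames(out) <- NULL
  class(out) <- c("precursor_stats", "data.frame")
  out
}

#' Weight, rank and relative rank per study
#'
#' The weight of a precursor is its presence fraction divided by its CV
#' (the signal-to-noise ratio 1/CV multiplied by presence). Within each
#' study, ranks ascend with weight so the highest-weight precursor receives
#' the maximal rank and relative rank 1; ties receive the average rank, and
#' the relative rank is the rank divided by the maximum rank observed in
#' that study. A CV of exactly 0 (perfectly reproducible intensities) maps
#' to infinite weight and hence maximal rank; precursors whose CV is
#' undefined (observed once) are ranked below all others.
#'
#' @param stats A `precursor_stats` data frame from
#'   [study_precursor_stats()].
#' @return The same data frame with `weight`, `rank` and `rel_rank` columns
#'   filled.
#' @export
weight_and_rank <- function(stats) {
  stats$weight <- ifelse(is.na(stats$cv), NA_real_,
                         ifelse(stats$cv == 0, Inf, stats$p_pres / stats$cv))
  stats$rank <- NA_real_
  stats$rel_rank <- NA_real_
  for (s in unique(stats$study_id)) {
    idx <- which(stats$study_id == s)
    w <- stats$weight[idx]
    w[is.na(w)] <- -Inf
    r <- rank(w, ties.method = "average")
    stats$rank[idx] <- r
    stats$rel_rank[idx] <- r / max(r)
  }
  stats
}

#' Aggregate relative ranks across studies
#'
#' Averages the relative rank of each precursor over the studies in which
#' it appears (absence is handled by the downstream project-count filter,
#' not by zero-imputation), and counts distinct studies and blood matrices
#' among those appearances. Proteotypicity is taken from the annotation
#' table, keyed by stripped sequence.
#'
#' @param per_study A ranked `precursor_stats` data frame (see
#'   [weight_and_rank()]), possibly spanning several studies.
#' @param annotations Optional annotation data frame with columns
#'   `peptide`, `protein_group`, `proteotypic` (see [read_annotations()]).
#' @return A `precursor_aggregate` data frame: `precursor`, `stripped_seq`,
#'   `protein_group`, `rel_rank_mean`, `n_projects`, `n_matrices`,
#'   `proteotypic`. The total number of studies seen is stored in the
#'   `"n_studies"` attribute.
#' @export
aggregate_relrank <- function(per_study, annotations = NULL) {
  if (is.null(per_study$rel_rank)) {
    stop("relative ranks not computed; call weight_and_rank() first")
  }
  grp <- factor(per_study$precursor, levels = unique(per_study$precursor))
  first <- !duplicated(per_study$precursor)
  out <- data.frame(
    precursor = per_study$precursor[first],
    stripped_seq = per_study$stripped_seq[first],
    protein_group = per_study$protein_group[first],
    stringsAsFactors = FALSE
  )
  out$rel_rank_mean <- as.numeric(tapply(per_study$rel_rank, grp, mean))
  out$n_projects <- as.integer(tapply(per_study$study_id, grp,
                                      function(x) length(unique(x))))
  out$n_matrices <- as.integer(tapply(per_study$matrix, grp,
                                      function(x) length(unique(x))))
  if (!is.null(annotations)) {
    m <- match(out$stripped_seq, annotations$peptide)
    out$proteotypic <- annotations$proteotypic[m]
    pg <- annotations$protein_group[m]
    out$protein_group <- ifelse(is.na(pg), out$protein_group, pg)
  } else {
    out$proteotypic <- NA
  }
  attr(out, "n_studies") <- length(unique(per_study$study_id))
  class(out) <- c("precursor_aggregate", "data.frame")
  out
}

#' Eligibility filter for panel candidates
#'
#' Keeps proteotypic precursors with mean relative rank at or above the
#' cutoff (inclusive), quantified in at least `min_projects` studies
#' (default: half the studies, rounded up) and at least `min_matrices`
#' blood matrices; then retains, per protein group, the top
#' `max_peptides_per_protein` peptides by mean relative rank (ties broken
#' by higher project count, then lexicographic sequence; multiple charge
#' states of one peptide are first collapsed to the best precursor).
#'
#' @param agg A `precursor_aggregate` data frame.
#' @param min_relrank Lower cutoff on the mean relative rank (inclusive).
#' @param min_projects Minimum number of studies; `NULL` means half of the
#'   studies seen during aggregation, rounded up.
#' @param min_matrices Minimum number of distinct blood matrices.
#' @param max_peptides_per_protein Per-protein peptide cap.
#' @return The selected subset of `agg` (one row per selected peptide,
#'   best precursor), with the pre-cap qualifying set in the
#'   `"qualifying"` attribute.
#' @export
eligibility_filter <- function(agg, min_relrank = 0.5, min_projects = NULL,
                               min_matrices = 2L,
                               max_peptides_per_protein = 3L) {
  if (is.null(min_projects)) {
    n_studies <- attr(agg, "n_studies")
    if (is.null(n_studies)) stop("min_projects not given and n_studies unknown")
    min_projects <- ceiling(n_studies / 2)
  }
  keep <- !is.na(agg$proteotypic) & agg$proteotypic &
    agg$rel_rank_mean >= min_relrank &
    agg$n_projects >= min_projects &
    agg$n_matrices >= min_matrices
  qual <- agg[keep, , drop = FALSE]
  # collapse charge states: best precursor per peptide
  ord <- order(qual$stripped_seq, -qual$rel_rank_mean, -qual$n_projects,
               qual$precursor)
  qual_pep <- qual[ord, , drop = FALSE]
  qual_pep <- qual_pep[!duplicated(qual_pep$stripped_seq), , drop = FALSE]
  # per-protein top-k by rel_rank_mean; ties: higher n_projects, then sequence
  ord <- order(qual_pep$protein_group, -qual_pep$rel_rank_mean,
               -qual_pep$n_projects, qual_pep$stripped_seq)
  qual_pep <- qual_pep[ord, , drop = FALSE]
  within <- stats::ave(seq_len(nrow(qual_pep)), qual_pep$protein_group,
                       FUN = seq_along)
  out <- qual_pep[within <= max_peptides_per_protein, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qualifying") <- qual
  class(out) <- c("precursor_aggregate", "data.frame")
  out
}

# Kyte-Doolittle hydropathy index per residue.
KYTE_DOOLITTLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Lehninger pKa set: termini and ionizable side chains.
PKA_LEHNINGER <- list(
  positive = c(Nterm = 9.69, H = 6.00, K = 10.53, R = 12.48),
  negative = c(Cterm = 2.34, D = 3.65, E = 4.25, C = 8.18, Y = 10.07)
)

check_canonical <- function(seq) {
  bad <- vapply(strsplit(seq, ""), function(x) any(!x %in% AA_CANONICAL),
                logical(1))
  if (any(bad)) {
    stop("non-canonical residue in sequence(s): ",
         paste(seq[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Mean Kyte-Doolittle hydropathy
#'
#' Arithmetic mean of the per-residue Kyte-Doolittle hydropathy indices;
#' positive values indicate hydrophobic peptides.
#'
#' @param seq Character vector of stripped peptide sequences.
#' @return Numeric vector of mean hydropathy values.
#' @export
hydropathy <- function(seq) {
  check_canonical(seq)
  vapply(strsplit(seq, ""), function(x) mean(KYTE_DOOLITTLE[x]), numeric(1))
}

#' Peptide net charge
#'
#' Henderson-Hasselbalch net charge at the given pH, summing the free
#' termini and the ionizable side chains (H, K, R positive; D, E, C, Y
#' negative) with the Lehninger pKa set.
#'
#' @param seq Character vector of stripped peptide sequences.
#' @param pH pH at which the charge is evaluated.
#' @return Numeric vector of net charges.
#' @export
net_charge <- function(seq, pH = 7.0) {
  check_canonical(seq)
  pos <- PKA_LEHNINGER$positive
  neg <- PKA_LEHNINGER$negative
  vapply(strsplit(seq, ""), function(x) {
    counts <- table(factor(x, levels = AA_CANONICAL))
    plus <- 1 / (1 + 10^(pH - pos["Nterm"]))
    minus <- 1 / (1 + 10^(neg["Cterm"] - pH))
    for (r in c("H", "K", "R")) {
      plus <- plus + counts[[r]] / (1 + 10^(pH - pos[[r]]))
    }
    for (r in c("D", "E", "C", "Y")) {
      minus <- minus + counts[[r]] / (1 + 10^(neg[[r]] - pH))
    }
    unname(plus - minus)
  }, numeric(1))
}

MISSED_CLEAVAGE_MOTIFS <- c("KK", "KR", "RR", "RK", "KP", "RP")

#' Physicochemical properties of peptides
#'
#' Length, mean Kyte-Doolittle hydropathy, net charge at pH 7, presence of
#' missed-cleavage-prone motifs (KK, KR, RR, RK, KP, RP), cysteine content
#' and N-terminal glutamine.
#'
#' @param seq Character vector of stripped peptide sequences.
#' @param pH pH for the net-charge calculation.
#' @return A data frame with one row per peptide.
#' @export
peptide_properties <- function(seq, pH = 7.0) {
  check_canonical(seq)
  data.frame(
    stripped_seq = seq,
    length = nchar(seq),
    hydropathy = hydropathy(seq),
    net_charge = net_charge(seq, pH = pH),
    missed_cleavage_motif = vapply(seq, function(s) {
      any(vapply(MISSED_CLEAVAGE_MOTIFS, function(m) grepl(m, s, fixed = TRUE),
                 logical(1)))
    }, logical(1), USE.NAMES = FALSE),
    has_cys = grepl("C", seq, fixed = TRUE),
    nterm_gln = startsWith(seq, "Q"),
    stringsAsFactors = FALSE
  )
}

#' Physicochemical filter
#'
#' Drops peptides whose length is outside [6, 25], that contain a
#' missed-cleavage motif, a cysteine, or an N-terminal glutamine — unless
#' the peptide is in the `exceptions` list, in which case it is retained
#' with its flags recorded. The per-peptide flag report records every
#' triggered rule regardless of the outcome.
#'
#' @param props A data frame from [peptide_properties()] (or a character
#'   vector of sequences, which is converted).
#' @param exceptions Character vector of peptide sequences exempt from
#'   exclusion.
#' @return A list with `kept` (retained subset of `props`) and `report`
#'   (all peptides, with logical flag columns and the `excluded` outcome).
#' @export
physicochemical_filter <- function(props, exceptions = character()) {
  if (is.character(props)) props <- peptide_properties(props)
  flags <- data.frame(
    stripped_seq = props$stripped_seq,
    flag_length = props$length < 6L | props$length > 25L,
    flag_missed_cleavage = props$missed_cleavage_motif,
    flag_cys = props$has_cys,
    flag_nterm_gln = props$nterm_gln,
    stringsAsFactors = FALSE
  )
  any_flag <- flags$flag_length | flags$flag_missed_cleavage |
    flags$flag_cys | flags$flag_nterm_gln
  is_exception <- props$stripped_seq %in% exceptions
  flags$is_exception <- is_exception
  flags$excluded <- any_flag & !is_exception
  list(kept = props[!flags$excluded, , drop = FALSE], report = flags)
}

#' Select an internal-standard peptide panel
#'
#' End-to-end selection: per-study presence/CV statistics, weight-based
#' ranking, cross-study aggregation, eligibility filtering and the
#' physicochemical filter.
#'
#' @param table A `quant_table` of study-pool series (light channel used).
#' @param annotations Annotation data frame (see [read_annotations()]).
#' @param exceptions Peptides exempt from the physicochemical filter.
#' @param include Peptides added to the panel regardless of selection
#'   outcome (e.g. a legacy panel), reported separately.
#' @param ... Passed to [eligibility_filter()].
#' @return A list with `panel` (selected peptide data frame), `aggregate`
#'   (all precursor aggregates), `physchem_report` and `included`.
#' @export
select_panel <- function(table, annotations, exceptions = character(),
                         include = character(), ...) {
  stats <- weight_and_rank(study_precursor_stats(table))
  agg <- aggregate_relrank(stats, annotations)
  elig <- eligibility_filter(agg, ...)
  pc <- physicochemical_filter(peptide_properties(elig$stripped_seq),
                               exceptions = exceptions)
  panel <- elig[elig$stripped_seq %in% pc$kept$stripped_seq, , drop = FALSE]
  list(panel = panel, aggregate = agg, physchem_report = pc$report,
       included = setdiff(include, panel$stripped_seq))
}
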