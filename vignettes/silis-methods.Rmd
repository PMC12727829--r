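---
title: "Methods: building and using SIL internal-standard panels with silis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and using SIL internal-standard panels with silis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silis)
```

## The problem

Bottom-up plasma and serum proteomics quantifies peptides, not proteins,
and the raw peak areas it produces are only relatively quantitative:
different LC-MS platforms, acquisition methods and batches return values
on scales that can differ by orders of magnitude for the same peptide.
Spiking a stable-isotope-labeled internal standard (SIL-IS) — a synthetic
copy of each target peptide, heavy-labeled on its C-terminal lysine or
arginine — lets every endogenous signal be expressed as a ratio to its
co-eluting standard, which cancels run-, batch- and platform-specific
multiplicative effects at the level of the individual peptide.

`silis` implements the full computational workflow around such a panel:
choosing which peptides belong in it, deciding how much of each standard
to mix, normalizing and quality-controlling the resulting data, anchoring
it to calibration curves, and measuring statistically how much the
standard improves cross-matrix and cross-platform agreement. Everything
is exercisable on seeded synthetic data with known ground truth.

## Panel selection: the weight-rank metric

For each precursor $p$ (a modified sequence plus charge state) in each
study-pool series $n$ we compute, over the series' repeated injections,

* the presence $\mathrm{PPres}(p,n)$: the fraction of runs in which the
  precursor was detected, and
* the coefficient of variation $\mathrm{CV}(p,n)$ on the linear intensity
  scale, the sample standard deviation over the mean of the observed
  intensities.

The weight $W(p,n) = \mathrm{PPres}(p,n)/\mathrm{CV}(p,n)$ is the
precursor's signal-to-noise ratio ($1/\mathrm{CV}$) multiplied by its
detection frequency. Within each study, precursors are ranked
*ascending* in weight, so the best precursor receives the maximal rank;
the relative rank is the rank divided by the maximum rank observed in
that study, placing it in $(0, 1]$ regardless of how many precursors a
study yielded. The direction matters: with an inclusive cutoff of 0.5 on
the cross-study mean relative rank, the kept precursors are the better
half, which guarantees that their average CV sits at or below the median
CV of the study (a property the test suite asserts on simulated pools).

Numerical choices, each of which the tests pin down:

* **Ties** receive the average rank — the standard convention, stable
  under permutation of the input.
* **CV = 0** (identical intensities in every run) maps to infinite
  weight and hence the top rank: perfect reproducibility must never be
  discarded on a division-by-zero technicality.
* **CV undefined** (a precursor observed only once in a series) leaves
  the weight undefined; such precursors are ranked below all others in
  that study rather than being silently dropped.
* The **CV uses the sample SD** ($n-1$ denominator); with the small
  replicate counts of study pools the choice is material and is stated
  here because no convention is universal.

Cross-study aggregation averages relative ranks over the studies *where
the precursor appears*; absence is handled by the project-count filter,
not by imputing zeros, so a precursor seen brilliantly in three studies
is not punished as if it had failed in five. Matrix coverage counts the
distinct blood-collection matrices (EDTA, citrate, heparin plasma,
serum) among those same appearances. Eligibility then requires
proteotypicity (taken from the annotation table, as a library property,
not recomputed from a proteome), mean relative rank at least 0.5
(inclusive), presence in at least half the studies (rounded up) and at
least two matrices; finally at most three peptides are kept per protein
group — ranked by mean relative rank, with ties broken by higher project
count and then lexicographic sequence so the output is deterministic.

The physicochemical filter drops peptides of length outside 6–25
residues, containing missed-cleavage-prone motifs (KK, KR, RR, RK, KP,
RP), cysteine, or an N-terminal glutamine — unless explicitly listed as
an exception, in which case the peptide is retained and its flags are
recorded in the report. Hydropathy is the mean Kyte–Doolittle index; the
net charge is the Henderson–Hasselbalch sum over termini and ionizable
side chains with the Lehninger pKa set at pH 7 — the upstream tooling
names only the functions it called, so the pKa set and pH are our
documented defaults, switchable by argument.

## Composing the concentration-matched standard

Spiking every standard at one concentration wastes material on
low-abundance peptides and swamps their endogenous signals. The composer
therefore estimates, from a dilution series of the heavy standard
against the fixed endogenous background, the spike level at which the
light/heavy ratio crosses 1 — interpolated linearly in log-log space,
since both signal and concentration are naturally log-scaled. Ratios
that never cross 1 inside the series are flagged (`above_range` /
`below_range`) and the nearest boundary level is reported rather than an
extrapolation.

Each peptide is then assigned the tier nearest in $\log_{10}$ space from
a configurable ascending tier list, defaulting to 10 / 100 / 500 / 2000
pg/µl — four roughly geometric levels spanning the two orders of
magnitude such standards typically cover. The published mixtures state
only the endpoints of this range, so the interior values here are
configuration with sensible defaults, overridable by a shipped
composition table. A two-orders screen and a one-order final rule
(`|log10(tier/endogenous)| <= 1`) are kept as two separate thresholds; a
peptide violating the final rule is flagged, not silently moved.
Exactly log-equidistant candidates go to the lower tier — spiking less
is the conservative error. Tier assignment is monotone in the
endogenous level by construction, and mixture totals are additive; both
are asserted as properties.

## Normalization and QC

Two strategies are implemented side by side:

* `norm_light`: one scalar factor per platform, the median of all
  endogenous (light-channel) intensities in that platform's study-pool
  runs; every light intensity on the platform is divided by it. This
  aligns global scales but cannot correct peptide-specific platform
  response differences.
* `ratio`: the light intensity divided by the matched heavy-standard
  intensity in the same run, matched on (modified sequence, charge,
  run). Because both channels share every multiplicative run- and
  platform-level factor, the ratio is *exactly* invariant to per-run
  channel-shared rescaling — an identity the tests assert bitwise. A
  missing or zero standard yields a missing ratio; no imputation happens
  at this stage.

Completeness filtering retains a peptide only when detected in strictly
more than two-thirds of a platform's samples. CVs come in a robust
flavor (scaled MAD over median, in percent) and a classic one (sample SD
over mean). The robust CV includes the 1.4826 normal-consistency
constant because the statistics environments these pipelines run in
include it by default in `mad()`; the constant is an argument, so
dropping it is one keyword away.

Per-peptide quantification precursors are chosen by a strict CV gate
(pool-replicate CV < 40%; the boundary value 40 fails, following the
printed wording "less than 40%"), then by abundance (the most abundant
surviving charge state has the best ionization efficiency). "Same trend"
agreement between same-protein peptides is not defined numerically
upstream; we operationalize it as a non-negative Spearman correlation
between the standard profiles across samples, and *flag* rather than
drop disagreements, since a negative correlation between two valid
peptides can reflect genuine isoform biology.

Fragment distribution profiles express each fragment's intensity as a
percentage of its run's total, take the median percentage per fragment
across runs, keep the top 12 and rescale to 100%. Working on per-run
percentages (rather than medians of raw intensities) is what makes the
profile exactly invariant to per-run rescaling. Retention-time QC
reports the median absolute light–heavy RT difference per peptide
(co-elution) and the classic CV of RTs across samples per peptide and
platform (stability), in minutes.

## Calibration

Calibration lines are fitted by weighted least squares with $1/x$
weights, the standard choice when response variance grows with
concentration. The blank has an undefined $1/x$ weight and is excluded
from the fit with a warning; it serves only to confirm negligible blank
signal, which is also why the detection limit is estimated from
replicate-curve intercept variability instead of blank noise:
$\mathrm{LOD} = 3.3\,\sigma/S$ and $\mathrm{LOQ} = 10\,\sigma/S$, with
$\sigma$ the sample SD of the y-intercepts across replicate curves and
$S$ the mean slope. The ratio $\mathrm{LOQ}/\mathrm{LOD} = 10/3.3$ is an
identity of the formulas and is asserted exactly.

The quantifiable range comes from back-calculation accuracy: a level
passes when the CV of its back-calculated concentrations across
replicates is at most 20%, relaxed to 40% when fewer than four levels
pass; the LLOQ/ULOQ are the lowest/highest passing levels. A curve is
"reportable" when at least four levels pass *and* the mean $r^2$ reaches
0.98 — the linearity requirement upstream has no printed number, so 0.98
is our documented default, adjustable by argument. Back-calculated
sample values outside the observed calibrant range are removed with a
reason code rather than clipped.

One estimator subtlety: the sample SD is consistent but biased low in
small samples ($\mathbb{E}[s] = c_4(n)\,\sigma$, $c_4(3) \approx
0.886$), so the *mean* LOD over many triplicate curves sits visibly
below $3.3\sigma/S$ even though each individual estimate is correct
usage. The formula-recovery experiment in the acceptance checks
therefore uses 25 replicate curves per simulation ($c_4(25) \approx
0.99$), a size chosen from the $c_4$ constant so that estimator bias is
negligible against Monte-Carlo resolution; the simulator's *default*
stays at the triplicates real curves use.

## The evaluation battery

* **Trend tests**: Kendall's tau-b with tie correction against the
  ordinal severity coding (healthy < mild < severe < critical), with a
  two-sided p-value from the tie-corrected normal approximation with
  continuity correction — matching the trend-test implementations these
  pipelines conventionally call — used at all sample sizes. Multiple
  testing is adjusted by Benjamini–Hochberg *within* each dataset or
  platform, since each platform is an independent experiment.
* **Paired Wilcoxon** signed-rank tests for matrix-to-matrix rank
  shifts: zero differences dropped, exact null for up to 25 untied
  differences, normal approximation with continuity correction beyond.
* **ICC**: ICC(3,k) (two-way mixed, average measures, consistency) for
  overall cross-platform reliability, ICC(2,1) (two-way random, single
  measures, absolute agreement) for platform pairs, both derived from
  the two-way ANOVA mean squares. Rows with missing values are removed
  listwise — the upstream description ("allowing missing values") is not
  operationalized anywhere, and listwise deletion is the conservative,
  reproducible reading.
* **KNN imputation** (k = 10) treats samples as observations (the
  transpose convention): a missing value of peptide *p* in sample *s* is
  the unweighted mean of *p* in the k samples nearest to *s* by
  Euclidean distance scaled by the number of co-observed peptides,
  matching the documented behavior of the canonical imputation tool.
* **Variance partitioning** fits, per peptide, the random-intercept
  model `value ~ (1|platform) + (1|severity)` by REML and reports each
  component's share of total variance. The REML fits go through `lme4`
  — the field-standard mixed-model engine — rather than a hand-rolled
  profiler; singular fits (a variance component at zero) are legitimate
  answers here, not failures, and are kept. Fit errors yield flagged
  missing fractions.
* **Bland–Altman**: bias, 1.96-SD limits of agreement, and t-based 95%
  confidence intervals for bias and limits, with the textbook standard
  error $s\sqrt{1/n + 1.96^2/(2(n-1))}$ for the limits.
* **Composite datasets** draw, per sample, one non-holdout platform
  uniformly at random (seeded) and take that platform's normalized
  values, preserving the sample set and hence the severity histogram
  exactly; the held-out platform never contributes, preventing leakage
  when the composite is compared against it. Per-sample uniform draws
  are used without per-platform balancing constraints — the simplest
  scheme consistent with "randomly taken... reflecting the sample and
  severity distribution".
* **Per-group regression** and **PCA scores** are thin, tested wrappers
  over ordinary least squares and SVD.

## The synthetic-data generators

The generators are first-class, tested code; their defaults *are* the
study conditions under which every property and acceptance check runs.

`simulate_study_pools()` (defaults: 6 studies × 8 runs, 200 precursors)
plants 50% "good" precursors (presence 0.97, CV 0.15) against "bad"
ones, half with low presence (0.55, CV 0.35) and half noisy (presence
0.97, CV 0.9), with log-normal baselines spanning orders of magnitude,
studies cycling through the four blood matrices, and two precursors per
protein so the per-protein cap is exercised without hiding planted
truth. Missingness is Bernoulli per run; an intensity-dependent
(logistic in log-intensity) mode emulates detection limits where that
matters.

`simulate_cohort()` (defaults: 40 samples over four severity levels,
3 platforms, 40 peptides, 5 pool replicates per platform) builds
`light = baseline × effect^step × response(platform, peptide) ×
run_factor × noise` and `heavy = spike × response × run_factor ×
noise`, with the run factor and the platform-by-peptide response factor
shared by both channels — so the true ratio is platform-free by
construction while raw intensities and platform medians are not. The
platform effect is deliberately *peptide-specific* (log-SD 0.7): a
purely global platform scale would be removed by median normalization
too, and the interesting contrast — ratio normalization beating median
normalization on platform variance — only exists when ionization
response differs per peptide per platform, as it does on real
instruments. Severity effects are multiplicative per step (default 1.4,
40% of peptides, half up, half down), measurement noise is 10% CV per
channel, and 5% of records are missing at random.

`simulate_calibration()` defaults to triplicate curves over the
five-fold serial dilution 0.064–1000 pg/µl (seven non-zero levels, the
eight-point design's blank optional), with a replicate-specific
intercept drawn from Normal(0, `intercept_sd`).

What the generators do **not** emulate: interference and co-elution
artifacts, intensity-dependent (heteroscedastic) noise on the cohort
scale, batch drift within a platform, isoform-driven divergence of
same-protein peptides, and non-multiplicative matrix effects. Passing
tests therefore demonstrate that the algorithms implement their
definitions and recover planted multiplicative structure — not that any
particular real dataset will show the same magnitudes.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale: 200-precursor
pools, 40-sample × 3-platform cohorts, 500-replicate calibration
recovery, 2000-peptide null calibration of the trend test. These sizes
put Monte-Carlo error well below the assertion margins while keeping a
full run in well under a minute per experiment. All randomness flows
from explicit integer seeds; the pipeline driver fans a single global
seed out into fixed per-stage sub-streams so any stage can be re-run in
isolation and reproduce byte-identical TSVs (hashes are written to a
manifest).

## Known limitations

* Protein-level roll-up (MaxLFQ-style inference) is deliberately out of
  scope; the workflow is peptide-centric.
* Calibration is strictly linear; 4PL/5PL fits and matrix-effect
  correction are not provided.
* The Kendall p-value is asymptotic at all n; for n below ~10 the exact
  permutation distribution would be preferable (the tests use
  enumeration oracles at those sizes, the production path does not).
* The spectral-library dialect (column names, `T`/`F` exclusion flags)
  is a documented choice; upstream tools carry channel information in
  processing flags whose on-disk refined form is not standardized.
* An "average relative CV ~ 0.5" style summary statistic is *not*
  implemented: the quantity is ambiguous between a relative rank and a
  CV ratio in its source context, and nothing downstream depends on it.
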