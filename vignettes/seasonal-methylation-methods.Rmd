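---
title: "Modelling seasonal methylation signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal methylation signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socewas)
```

## The problem

A cyclical exposure — here the calendar date of conception — cannot be
entered into a linear model as a raw day-of-year: day 365 and day 1 are a
day apart, not a year. `socewas` models the exposure with Fourier
(cosinor) regression: the conception date is mapped to an angle
$\theta \in [0, 2\pi)$ (1 January $= 0$) and enters the per-CpG model as a
sin/cos pair,

$$M_{ij} = \alpha_{0j} + \sum_k \alpha_{kj} x_{ik} +
  \beta_j \sin\theta_i + \gamma_j \cos\theta_i + \varepsilon_{ij},$$

which is a sinusoid with free amplitude and phase. No seasonal window is
assumed in advance; the data decide when methylation peaks. With one pair
of terms the modelled maximum and minimum are exactly half a year apart;
higher-order pairs (`fourier_pairs > 1`) allow more complex annual shapes
but are off by default.

All modelling is done on M-values ($\log_2$ odds of methylation), the
scale on which array methylation is closest to homoscedastic Gaussian;
amplitudes are reported back on the beta (fraction methylated) scale,
which is what a biologist reads.

## The fitting pipeline, step by step

1. **Outlier masking** (`remove_outliers`). Per CpG, beta values outside
   $[Q_{25} - 3\,\mathrm{IQR},\; Q_{75} + 3\,\mathrm{IQR}]$ are set to
   missing. Quartiles use type-7 linear interpolation (the R default) —
   stated explicitly because the masked set depends on the convention.
   Masking is applied on the beta scale, in a single pass (quartiles are
   not recomputed after masking); both choices are defaults a user can
   audit, and the single-pass rule makes the operation idempotent.
2. **Transform** (`beta_to_m`). Betas are clamped to
   $[10^{-6}, 1 - 10^{-6}]$ before the logit so boundary values cannot
   produce infinities.
3. **Fit** (`fit_cosinor` / `run_ewas`). Ordinary least squares of the
   full model and of the covariate-only reduced model on the identical
   retained samples. `run_ewas` fits CpGs that share a post-masking
   sample pattern through a single QR decomposition; this is purely an
   implementation detail — tests assert numerical identity with the
   per-CpG route.
4. **Test** (`lrt_pvalue`). Gaussian likelihood-ratio statistic
   $n \log(\mathrm{RSS}_{\mathrm{reduced}}/\mathrm{RSS}_{\mathrm{full}})$
   against $\chi^2$ with 2 df per Fourier pair. At moderate sample sizes
   this statistic is mildly anti-conservative relative to the exact
   F-test (at $n = 250$ with eleven regressors the expected rejection at
   $\alpha = 0.05$ is about 0.057); we keep the likelihood-ratio
   convention because it generalises beyond the Gaussian case and is the
   standard choice in this literature.
5. **Correct** (`fdr_adjust`). Benjamini–Hochberg across CpGs. The
   assumed number of tests `m` defaults to the number of CpGs supplied
   but can be overridden with an array-background size when a subset of
   loci is tested against a genome-wide correction standard.
6. **Summarise** (`amplitude_phase`). The fitted curve is evaluated on a
   365-point daily grid at a covariate reference (numeric covariates at
   their means, 0/1 indicator columns at their modal value — the paper
   trail for amplitudes rarely states the reference, so we fix one and
   document it), back-transformed to the beta scale, and summarised as
   amplitude = (max − min) × 100 and the peak/nadir days. The grid is
   authoritative because it extends unchanged to multi-pair fits; for the
   single-pair model the closed form (peak angle $\mathrm{atan2}(\beta,
   \gamma)$, M-scale amplitude $2\sqrt{\beta^2 + \gamma^2}$) agrees
   within one grid step and is used as a cross-check. Because the
   logit is monotone, peak and nadir days are identical on either scale.
   Angles convert to days with a 365.25-day year.

A genomic inflation factor (`inflation_lambda`, median 1-df chi-square
quantile over 0.4549) is attached to every EWAS table: seasonal exposures
with many-locus effects can legitimately inflate it, so it is a
diagnostic, not a gate.

## Hits, controls, replication

Hits (`select_soc_cpgs`) need both statistical significance (q < 0.05)
and a material effect (amplitude ≥ 4 percentage points). Because hits
concentrate at intermediately methylated loci, naive comparisons against
the array background confound "seasonal" with "intermediate"; matched
controls (`select_matched_controls`) therefore pair every hit with a
background CpG whose beta distribution is indistinguishable by a
two-sided Kolmogorov–Smirnov test (p > 0.1). Matching is greedy and
one-to-one in seeded shuffled order — the simplest reproducible scheme;
an optimal-assignment variant was considered and rejected as needless
complexity for a screening control. Random controls are a uniform draw
from the admissible background.

Replication between two EWAS tables (`replication_stats`) reports the
Spearman correlation of peak days on linear day-of-year values — the
field's convention — with a circular option (`circular_phase = TRUE`)
because the linear statistic is sensitive to the 1 January cut when peaks
straddle the new year; paired amplitude differences are tested with a
Wilcoxon signed-rank test using the Pratt treatment of zero differences
(zeros keep their ranks but contribute nothing), so a table compared with
itself cleanly reports p = 1.

## Genomic context

CpG clusters (`build_clusters`) chain neighbours at most 5 kb apart
(inclusive at the boundary). De-clustering (`decluster`) keeps one random
member per cluster and all singletons, so a run of correlated CpGs
contributes one unit of evidence. Enrichment (`overlap_enrichment`) is a
two-sided Fisher exact test on (set vs rest-of-background) ×
(overlap vs not); the reported fold is the set rate over the
whole-background rate. The test choice is ours — published folds in this
area typically come without a named test — and the exact test is the
defensible default at the small counts involved. The cluster-adjusted
variant de-clusters set and background over 100 seeded draws and reports
the median fold and p, since a single draw would leave the answer hostage
to one random selection. Proximity curves (`proximity_curve`) report the
proportion of the (de-clustered) set within each distance of a track, with
percentile CIs from 1000 bootstrap resamples of the CpG set; a CpG inside
an interval has distance 0.

Gametic classification (`classify_gamete_status`) applies the germline
DMR thresholds: oocyte gDMR = sperm < 25% and oocyte > 75%; sperm gDMR
symmetric; sperm hypomethylation alone is inclusive (≤ 25%). The ≤/<
boundary asymmetry is kept deliberately, as both rules are quoted
verbatim in the source definitions; a CpG at exactly 25% sperm
methylation is "sperm hypomethylated" but never an oocyte gDMR.

## Genetic analyses

SNPs enter as allelic dosages, filtered to MAF > 10% and at least ten
minor-allele homozygotes (so the dosage-2 class cannot be driven by a
handful of individuals). The mQTL scan is two-step to maximise power for
the dominant cis architecture: first only SNPs within 1 Mb of each query
CpG, with FDR within that family; then all SNPs, with FDR over the full
family. Effects come from `M ~ covariates + G`, computed by
Frisch–Waugh residualisation (identical to the full regression, verified
against `lm` in tests). Variance explained is
$\Delta\mathrm{adj}R^2 = \mathrm{adj}R^2(\mathrm{covs + mQTL}) -
\mathrm{adj}R^2(\mathrm{covs})$ on identical samples; adjusted $R^2$
normalises across CpGs with different mQTL counts and can be slightly
negative for null SNPs. The gene-by-season scan interacts each dosage
with the CpG's dominant Fourier term (the one with the smaller marginal
p in the main fit; ties choose sin). The genotype–season confounding
check offers a continuous regression mode (dosage on sinθ + cosθ, joint
F-test — the default, since it uses the full exposure) and a dichotomised
mode (allele-count chi-square between two user-specified season windows)
mirroring tools that require a discrete phenotype.

## The synthetic cohort generator

`simulate_cohort` produces the data structure the analysis assumes, with
truth recorded for every CpG:

* **Conception dates**: von Mises on the year circle; concentration 0
  (the default) is uniform — cohort papers in this area rarely publish
  the empirical conception-date distribution, and uniform is the neutral
  choice.
* **Seasonal signal**: added on the logit2 scale as
  $a\cos(\theta - \theta_{\mathrm{peak}})$ with half-amplitude
  $a = 0.173$ by default, i.e. ≈ 6 percentage points of beta-scale
  amplitude at the intermediate baseline 0.5 — a typical effect size at
  seasonally responsive loci. Per-CpG peak days spread around day 240
  (late August, the local rainy season) with SD 45 days
  (`peak_day_sd`), reproducing heterogeneous year-round phases; the
  beta-scale amplitude is baseline-dependent by construction.
* **Baselines**: seasonal CpGs sit in an intermediate-methylation
  hotspot (0.45–0.55); the background follows the usual bimodal array
  profile (40% low, 40% high, 20% intermediate).
* **Nuisance structure**: additive logit2-scale sex/age/batch/
  intervention effects plus latent cell-composition factors with random
  per-CpG loadings (SD 0.1), recoverable by PCA. Residual noise SD 0.3
  on the M scale. No interactions are generated unless a gene-by-season
  effect is configured explicitly.
* **Genotypes**: Hardy–Weinberg dosages at MAFs in (0.10, 0.5]; every
  emitted SNP passes the common-variant filters by construction
  (resampled otherwise — at small n this implicitly pushes MAFs upward).
  A configurable subset of CpGs receives a dedicated cis-SNP (10 kb
  away) with a per-dose effect of 0.15 M-units, which explains ≈ 9% of
  methylation variance under the default noise.
* **Coordinates and tracks**: CpGs are spaced 50 kb apart (singletons)
  except for a configurable fraction of seasonal CpGs placed in ≤ 5 kb
  pairs; annotation tracks overlap CpGs at a background rate of 5% and
  at seasonal CpGs at a rate chosen so the realised fold — set rate over
  whole-background rate, which includes the set — matches the requested
  enrichment fold.
* **Replication cohorts**: `simulate_replication_cohort` redraws
  samples, genotypes and noise while holding the per-CpG truth fixed,
  optionally scaling all true amplitudes (e.g. 0.5 to emulate
  attenuation of the seasonal effect with age), so cross-cohort
  replication and attenuation statistics have a ground truth.

Everything is deterministic given the configuration seed. What the
generator does **not** emulate: probe chemistry and normalisation
artefacts, heavy-tailed outliers (real cohorts average ~1 masked outlier
per CpG; the Gaussian generator produces almost none, so the outlier rule
is exercised by dedicated fixtures rather than by the cohort), linkage
disequilibrium between SNPs, and fine-scale genomic feature geometry.
Passing tests on synthetic cohorts therefore demonstrate statistical
correctness of the machinery, not robustness to array artefacts.

## A note on PC adjustment and widespread exposure effects

Adjusting for unsupervised principal components of the methylation matrix
is standard practice and is what the null-calibration checks use. But PCs
are estimated from the outcome matrix: when a non-trivial fraction of
loci (here 10%) share a seasonal signal, the leading PCs absorb the
exposure itself and power collapses. The FDR/power validation therefore
adjusts for the known covariates only. In real analyses with suspected
many-locus exposure effects, the number of PCs deserves the same
scrutiny as any other model choice — an inflation factor well above 1
with PCs included is one symptom.

## Numerical and edge-case choices

* Rank-deficient designs abort with the offending column names rather
  than silently dropping terms (constant θ makes the Fourier pair
  collinear with the intercept).
* A fit with exactly zero seasonal coefficients reports amplitude 0 and
  a missing peak day.
* Grid ties in the amplitude search resolve to the first grid day, so
  results are reproducible byte-for-byte.
* KS matching refuses (with the target named) when the background is
  exhausted rather than returning a weaker match.
* An empty annotation track yields an undefined fold with the Fisher p
  still reported (it is 1).
* All file formats are plain text; BED intervals are converted between
  0-based half-open (on disk) and 1-based closed (in memory) at the I/O
  boundary, and CpG/SNP positions are 1-based throughout.

## Problem sizes used in the shipped validation

The test-suite and acceptance script exercise the pipeline at the scale
of a realistic single-cohort study: 250 samples × 2000–5000 CpGs for
calibration, FDR and power (20 replicates of the mixed cohort); 200
replicates of single-CpG amplitude/peak recovery; 284 samples × 100
replicates for mQTL detection and variance decomposition; 10,000 CpGs for
enrichment-fold recovery. These sizes make every check sharp enough to
fail on a real defect while completing in minutes on one CPU.
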