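---
title: "Methods: two-sample MR of gut microbiota on IgAN, and its validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of gut microbiota on IgAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgut)
```

## The causal model and its assumptions

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure (here: the relative abundance of a gut taxon, or
a circulating metabolite) on an outcome (IgAN risk), using only GWAS
summary statistics from two non-overlapping samples. Writing γ_j for the
effect of variant j on the exposure and Γ_j for its effect on the outcome,
a valid instrument satisfies the three IV assumptions — association with
the exposure, independence from confounders, and no path to the outcome
except through the exposure — under which Γ_j = θ·γ_j and every Wald ratio
Γ_j/γ_j estimates the causal effect θ (log-odds of IgAN per SD of
exposure). Horizontal pleiotropy adds a direct effect α_j, giving
Γ_j = θ·γ_j + α_j; the estimator battery differs exactly in what it
assumes about the α_j:

* **IVW** assumes α_j = 0 (or mean-zero *balanced* pleiotropy); it is the
  most efficient estimator and the pipeline's primary result.
* **MR-Egger** allows directional pleiotropy provided InSIDE holds
  (α_j independent of γ_j): the slope estimates θ, the intercept the mean
  pleiotropy. Power is much lower; the intercept's p-value is the
  first-line pleiotropy test.
* **Weighted median** is consistent while instruments carrying ≥ 50% of
  the weight are valid.
* **Weighted mode** is consistent while the largest cluster of instruments
  with a common ratio is valid.

When the methods disagree, IVW is reported as primary and the
classification below applies to its p-value.

## Instrument screening parameters

All thresholds are configurable in `run_pipeline()`'s `params`; defaults
are the study's screening rules:

| parameter | default | meaning |
|---|---|---|
| `p_threshold` | 1e-5 | locus-wide instrument significance |
| `p_threshold_metabolite` | 5e-5 | relaxed threshold for metabolites (too few variants reach 1e-5) |
| `r2_max`, `window_kb` | 0.001, 10000 | greedy LD clumping: keep the most significant variant, drop neighbours with r² > 0.001 or (when no LD estimate exists) within 10,000 kb |
| `eaf_min` | 0.01 | allele-frequency floor, applied to the *minor* allele by default (`symmetric = FALSE` recovers the literal effect-allele reading) |
| `f_min` | 10 | single-SNP instrument strength, F = (R²/(1−R²))·(N−K−1)/K with R² = 2·EAF(1−EAF)β² and K = 1 |
| `outcome_p_cut` | 0.05 | drop instruments associated with the outcome |
| `palindrome_eaf_window` | 0.08 | drop A/T and C/G variants with exposure EAF within 0.08 of 0.5 |

Three of these deserve comment. First, the F formula is often printed with
the algebraically negative form R²/(R²−1); the implementation uses
R²/(1−R²), the standard form that the F ≥ 10 screen presupposes. Second,
per-SNP R² comes from the standardized-scale identity 2·EAF(1−EAF)β², and
K = 1 because strength is screened per instrument before the final
instrument count is known. Third, dropping frequency-ambiguous palindromic
variants is the conservative standard; harmonization otherwise aligns
outcome effects to the exposure's effect allele, negating β and reflecting
EAF when the alleles are swapped, and dropping inconsistent pairs.

A deliberate property of the prescribed screen is worth knowing: excluding
instruments with outcome p < 0.05 *selects against* the strongest signals
when the true effect is large, attenuating the estimate toward the null.
With effects of the size seen for gut taxa (OR ≈ 1.2) the attenuation is
mild, but the pipeline should not be expected to recover very large
simulated effects unbiasedly through the full screen.

## Multiple testing and verdicts

Bonferroni correction is applied per taxonomic level: 0.05 divided by 131
(genus), 35 (family), 20 (order), 16 (class), 9 (phylum), 15 (metabolite).
A p-value below the corrected threshold is **significant**; in
[threshold, 0.05) it is **nominal**; otherwise **null**. Both comparisons
are strict. The metabolite divisor is 15 even though only 12 metabolites
are named in the source data description; the divisor actually used for
correction is the published one, and both are configurable through
`bonferroni_scheme()`.

```{r}
sch <- bonferroni_scheme()
sapply(c("genus", "family", "order", "class", "phylum", "metabolite"),
       bonferroni_threshold, scheme = sch)
```

## Sensitivity battery

* **Cochran's Q** with J−1 df against the fixed-effect IVW estimate.
* **Egger intercept** t-test (J−2 df).
* **MR-PRESSO**: the observed residual sum of squares — each instrument's
  outcome-variance-weighted squared residual about the IVW fit *excluding
  that instrument* — is compared to a parametric-simulation null
  (`n_sim = 1000` by default), with the add-one rule
  p = (1 + #{RSS\* ≥ RSS})/(n_sim+1), so p ≥ 1/(n_sim+1). Per-instrument
  residuals give outlier p-values, Bonferroni-adjusted by J and flagged at
  adjusted p ≤ α (inclusive, so α = 1 flags everything and triggers the
  no-estimate error path). The distortion test compares the estimate shift
  after outlier removal to shifts under random same-size removals, and is
  only defined when at least one outlier is found.
* **Leave-one-out**: IVW excluding each instrument in turn; a row is
  flagged when its exclusion flips the sign or removes nominal
  significance.

A practical caveat established during validation: with few instruments
(J ≈ 10) a single gross outlier distorts the leave-one-out fitted values
of the *other* instruments enough that a second variant is occasionally
co-flagged. At J = 20 (5% contamination) identification is exact across
seeds, which is why the demonstration and tests use that size. This is a
property of the PRESSO construction, not of this implementation.

## The synthetic-data generator

`simulate_summary_pair()` embodies the causal diagram above:
γ_j ~ N(`gamma_mean`, `gamma_sd`²); observed exposure effects add noise
with SE 1/√(2·EAF(1−EAF)·n_exp) (standardized continuous trait,
n_exp = 18,340 — the scale of the microbiota GWAS meta-analysis);
outcome effects are θγ_j + α_j plus noise with the binary-trait SE
1/√(2·EAF(1−EAF)·n_out·cf(1−cf)) (n_out = 628,000, case fraction 0.01 —
IgAN is rare). Pleiotropy modes: `none`, `balanced` (mean-zero),
`directional` (mean 0.02, SD 0.01 — comparable to θ·γ̄ for OR ≈ 1.2, so
the induced IVW bias is visible but not absurd), and `inside_violating`
(corr(α, γ) = 0.6). EAF ~ U(0.05, 0.95); instruments are placed > 10 Mb
apart across chromosomes and the LD table is empty, i.e. truly independent
— clumping behaviour is tested with purpose-built block fixtures instead.

Default instrument strength is `gamma_mean = 0.15`, `gamma_sd = 0.08`:
heterogeneous single-SNP F values from ~10 to several hundred, resembling
a post-screen microbiota instrument set. The *strong-instrument* studies
(parameter recovery, directional-pleiotropy robustness) instead use
`gamma_mean = 0.3`, `gamma_sd = 0.12`, giving I²_GX ≈ 0.99. The reason is
regression dilution: MR-Egger's slope attenuates by roughly the
measurement-error fraction of the exposure-effect variance, and with
weaker settings that bias (up to ~0.02 on the log-odds scale) is of the
same order as the Monte-Carlo error of a 200-replicate study, so Egger's
unbiasedness claim only holds where its NOME premise does. This
sensitivity is a known limitation of Egger regression, not a tuning knob.

The clinical-cohort generator draws per-group abundances from logit-normal
distributions (typical abundance ≈ 0.22 IgAN, 0.08 healthy, 0.11 other
glomerular disease; SD 0.5 on the logit scale) and generates 24-h
albuminuria linearly in logit abundance with noise calibrated against the
realized spread so that corr(logit abundance, albuminuria) equals
`target_r` (default 0.85) — the calibration is exact on the generative
(logit) scale; on the raw-abundance scale the correlation is very slightly
lower. Negative albuminuria draws (rare at the default mean of 1.3 g/24 h)
truncate at zero. eGFR is generated around group means (93.5 / 55.5 / 17.9
mL/min/1.73 m²) with a configurable dependence on abundance.

What the generator does *not* emulate: LD between instruments, winner's
curse in instrument discovery, sample overlap between exposure and outcome
GWAS, compositionality of relative abundances, sequencing noise, or
covariate structure in the cohort. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data pathologies.

## Numerical choices

* Wald-ratio SE is the first-order delta approximation se_out/|β_exp|.
* IVW random-effects inflation is scale-up only (never below the
  fixed-effect SE); Egger applies the analogous overdispersion rule with
  J−2 df.
* Egger orients instruments to β_exp > 0 before fitting (the standard
  convention; the fit is solved by closed-form weighted normal equations).
* Weighted-median interpolation uses standardized cumulative weights
  s_j = (Σ_{i≤j}w_i − w_j/2)/Σw; a dominant instrument (> 50% weight)
  therefore pins the estimate to within the minority weight share of its
  ratio, not exactly to it.
* Weighted-mode bandwidth is 0.9·min(sd, MAD)·J^(−1/5) times
  `bandwidth_factor`; the density argmax is located on a 512-point grid
  and refined with `optimize()` at tolerance 1e-9.
* Bootstrap SEs (median, mode) resample β_exp and β_out from their normal
  sampling distributions; `n_boot = 1000` and an explicit seed.
* LD clumping breaks p-value ties lexicographically on variant id, making
  the greedy order — and hence the result — fully deterministic.
* Youden-cutoff ties resolve to the lowest maximizing threshold, and the
  returned cutoff is the midpoint of the gap to the next observed score
  (a flat curve returns the lowest threshold with a degeneracy flag).
* Classification is strict (>) at the biomarker cutoff.
* The group-comparison screen is Shapiro-Wilk per group plus Bartlett's
  homogeneity test, each at 0.05; constant data short-circuit to a
  degenerate result (statistic 0, p 1) rather than an error.
* Missing LD pairs count as r² = 0; the physical window applies only to
  pairs without an LD estimate.

## Problem sizes used by the tests and acceptance script

Monte-Carlo suites use 200 replicates (calibration: θ = 0, J = 50;
recovery: θ = ln 1.2, J = 30 strong instruments), PRESSO demonstrations
J = 20 with `n_sim = 1000`, the oracle-agreement suite 100 random
instances, and the end-to-end study five exposures × J = 50. These sizes
put Monte-Carlo error well below the tolerances being asserted while
keeping a full run in tens of seconds.

## Known limitations

* No MR-RAPS, multivariable MR, or Steiger filtering; no FDR alternative
  to Bonferroni.
* No proxy-SNP search, liftover, or reference-panel LD estimation: the LD
  table must be supplied (or instruments assumed independent).
* Bootstrap (not DeLong) CIs for the AUC.
* The reported clinical metrics of a 10-vs-10 cohort are coarse-grained
  (multiples of 1/10); small-sample ROC quantities should be read
  accordingly.
* Egger estimates attenuate under weak instruments (see above); the
  package reports but does not correct for this (no SIMEX).
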