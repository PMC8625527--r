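---
title: "Gene-level methylation scoring and two-step MR: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level methylation scoring and two-step MR: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simpomr)
```

This vignette explains the statistical models the package implements, the
choices made where the methods left room, and what the simulation-based
tests do and do not establish.

## The SIMPO score

Methylation arrays report a beta value (a methylated fraction in [0, 1])
for each CpG probe, and a gene's probes split between its promoter and its
body. Promoter and body methylation carry different, weakly correlated
signals, and the *difference* between them tracks expression better than
either alone. The SIMPO score makes that contrast per gene and sample:

$$\mathrm{score} = \frac{\bar x - \bar y}{S_w\sqrt{1/m + 1/n}},\qquad
S_w = \sqrt{\frac{(m-1)S_1^2 + (n-1)S_2^2}{m+n-2}},$$

with $\bar x, S_1^2$ the mean and variance over the $m$ body probes and
$\bar y, S_2^2$ over the $n$ promoter probes. This is exactly a pooled
two-sample t statistic across the gene's probes, so it is nominally
$t(m+n-2)$ when probe values within a region are exchangeable.

Two details deserve comment:

* **Pooled-SD denominator.** `compute_simpo_scores()` uses the pooled
  variance with denominator $m+n-2$ and takes the square root, which is
  what the $t(m+n-2)$ form requires. A variant with denominator $m+n+1$
  circulates in some descriptions of the score; it is exposed via
  `sw = "printed"` for comparison but is internally inconsistent with the
  t distribution and is not the default.
* **Eligibility.** A gene needs at least two probes in each region —
  otherwise $S_1^2$ or $S_2^2$ is undefined. Missing probe values are
  dropped per sample; a sample whose missing values push a region below
  two probes is unscored for that gene. Zero pooled SD with unequal means
  (constant probes) yields `NA` with a warning rather than an infinite
  score.

### The two screens and their intersection

`diff_methylation_simpo()` compares scores between groups with a Welch
t test by default. The methods literature often says only "t test"; Welch
is the safer reading under unequal group sizes (the default cohort is
179 versus 190) and costs essentially nothing when variances are equal. A
pooled-variance option (`var_equal = TRUE`) is provided. Genes pass at
p < 0.05.

`dmp_scan()` is the traditional probe-level alternative: each probe is
tested with a linear model on the group indicator — for two groups the
model F statistic is the squared pooled t — and p-values are converted to
q-values by Benjamini–Hochberg step-up (via `stats::p.adjust`). BH was
chosen over Storey's estimator because the method naming is ambiguous in
common usage, BH is deterministic, and BH equals Storey with $\pi_0 = 1$;
probes pass at q < 0.001. Significant probes collapse to unique gene
symbols and `intersect_gene_lists()` takes the exact-match intersection
with the gene-level list.

## Two-sample Mendelian randomization

All estimators are written from their defining formulas. Given harmonized
per-SNP effects $(\hat\gamma_j, \hat\Gamma_j)$ of a variant on exposure
and outcome, the Wald ratio is $\hat\Gamma_j/\hat\gamma_j$ with
first-order SE $\sigma_{Y_j}/|\hat\gamma_j|$, and:

* **IVW** is the weighted mean of ratios with weights
  $w_j = \hat\gamma_j^2/\sigma_{Y_j}^2$ — algebraically identical to
  weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin
  (a property the tests assert to 1e-10). The default SE model is
  multiplicative random effects: the fixed-effect SE
  $(\sum w_j)^{-1/2}$ inflated by $\max(1, \sqrt{Q/(J-1)})$, matching
  common practice; a fixed-effect flag exists. P-values use the normal
  reference.
* **Weighted median**: ratios are sorted, weights normalized, and the
  estimate interpolates the cumulative weight positions
  $p_k = \sum_{i\le k} w_i' - w_k'/2$ at $p = 0.5$. It is consistent
  when valid instruments carry more than half the weight. The SE comes
  from a parametric bootstrap of $(\hat\gamma_j, \hat\Gamma_j)$ with an
  explicit seed and `n_boot` (default 1000) — the point estimate never
  depends on the bootstrap.
* **MR-Egger** regresses $\hat\Gamma$ on $\hat\gamma$ with a free
  intercept and weights $1/\sigma_{Y_j}^2$, after flipping each pair so
  $\hat\gamma_j \ge 0$ (the published orientation convention; the fit is
  not invariant to allele orientation). The slope is the causal estimate;
  the intercept estimates average directional pleiotropy and is judged
  ignorable when its p-value (t reference, $J-2$ df, SE floor-inflated by
  the residual scale as for IVW) exceeds 0.05. Egger's consistency needs
  the InSIDE assumption — pleiotropy independent of instrument strength.
* **Diagnostics**: Cochran's Q at the IVW estimate
  ($\chi^2_{J-1}$) and leave-one-out IVW re-estimation per SNP.
* **Odds ratios** are $e^\beta$ with 95% Wald intervals
  $e^{\beta \pm 1.96\,\mathrm{se}}$, read as risk change per SD of
  exposure.

### Harmonization

Instruments pass at p strictly below 5×10⁻⁸. `harmonize()` inner-joins on
rsID and aligns the outcome to the exposure's effect allele, trying a
direct match, a swap, and both again after strand complement; swapped
matches negate the outcome beta and complement its EAF. Palindromic SNPs
(A/T, C/G) cannot be oriented by letters, so effect-allele frequencies
decide — both must sit outside 0.5 ± 0.08 (a conventional, conservative
window) or the SNP is excluded with reason `"ambiguous palindromic"`.
Exclusions are returned with reason codes and counted in the pipeline
manifest, because downstream gene/SNP counts are exclusion-sensitive.

No LD clumping is performed: reference panels would require external
downloads, and the simulators generate independent instruments. With real
GWAS inputs the user must supply pre-clumped instruments — a documented
limitation.

### Two-step mediation

`run_two_step()` runs the full suite for exposure → mediator and
mediator → outcome and reports the mediated effect as the product of the
two IVW betas. The product is the natural point estimate under linear
structural equations; a delta-method SE
$\sqrt{b_2^2 s_1^2 + b_1^2 s_2^2}$ is attached, while a formal mediation
test is deliberately out of scope. Steps whose Egger intercept test
rejects (p ≤ 0.05) are flagged rather than dropped.

## The synthetic-data generators

`simulate_methylation_cohort()` draws gene-level promoter and body
baselines on the logit scale (promoters hypomethylated near logit −1.5,
bodies near +1.0, both with SD 0.5), per-probe offsets (SD 0.3), and
per-cell noise (`noise_sd`, default 0.5); effects are added to treated
samples' body-probe logits and everything maps through the inverse logit.
Working on the logit scale keeps betas in (0, 1) without the boundary
artifacts of truncated Gaussians. Defaults are 179 + 190 samples and 2–4
probes per region. What the generator does *not* emulate: probe-level
technical artifacts (dye bias, batch), spatial correlation along the
genome, cell-type mixture, and the empirical bimodality of array-wide
beta distributions — so passing tests demonstrate correctness of the
statistics, not robustness to array preprocessing issues.

`simulate_gwas_pair()` draws instrument strengths
$\gamma_j \sim N(0.3, 0.1)$ by default, outcome effects
$\theta\gamma_j + \alpha_j + e_j$, and standard errors from the standard
GWAS form $1/\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}$ with
n = 100,000 — strong instruments, appropriate for testing estimator
calibration rather than weak-instrument behavior. Pleiotropy draws are
independent of $\gamma$ (InSIDE) unless `inside = FALSE`, which makes
them track instrument strength to demonstrate Egger's failure mode; a
`frac_pleiotropic` field controls the share of invalid instruments. About
half the outcome rows are stored on the opposite allele orientation so
harmonization is always exercised. Generated p-values satisfy
$p = 2\Phi(-|\beta/\mathrm{se}|)$ exactly. LD between SNPs and realistic
microbiome abundance distributions are not simulated.

All simulators are pure functions of their config (the seed is a config
field) and restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Constant probes in `dmp_scan()` get statistic 0 and p = 1; the equality
  of group means is tested with a relative tolerance of 1e-8 to absorb
  floating-point dust in row-wise moment computation.
* `ivw_estimate()` refuses a single instrument unless
  `allow_single = TRUE`, in which case it degenerates to the Wald ratio;
  Egger and the weighted median require three instruments and say so.
* Egger refuses fits where the oriented exposure effects have (numerically)
  zero spread, rather than returning an unstable slope.
* Ties in the weighted median are handled by the interpolation rule
  itself; an exact hit of the 0.5 position returns that ratio.
* TSV output is written at full precision so write-then-read round trips
  are exact.

## Problem sizes in the tests and acceptance script

The replicate studies use 2000-gene null cohorts at 20 + 20 samples for
screen calibration; 200 replicates of 40-gene cohorts (5 planted genes,
logit effect 1.0, 50 + 50 samples) for end-to-end recovery; and 200–500
replicate GWAS simulations with 50 instruments for IVW recovery/coverage,
Egger size/power, weighted-median robustness and the two-step null. These
sizes give Monte-Carlo SEs comfortably inside the asserted bands while
keeping a full run fast on one CPU.

## Known limitations

* With the minimum of two probes per region the score is a $t(2)$-type
  variable with very heavy tails, and the downstream Welch t test is
  mildly conservative: the observed null rejection rate at
  $\alpha = 0.05$ is about 0.040–0.045 rather than 0.050. More probes per
  region move it to nominal.
* The mediated effect has no formal inference beyond the delta SE.
* Harmonization trusts the reported EAFs for palindromic SNPs; when EAFs
  are absent, every palindromic SNP is dropped.
* Instruments are assumed independent (no LD clumping, see above).
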