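---
title: "Two-sample MR with two-step mediation: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

`mrmediate` estimates how much of the causal effect of an exposure on a
disease outcome runs through an intermediate molecular trait, using only
GWAS summary statistics from three non-overlapping cohorts. The motivating
setting is immunophenotype exposures (hundreds of flow-cytometry traits from
a small cohort, n ≈ 3,757), plasma-metabolite mediators (n ≈ 8,299), and a
large binary heart-failure outcome GWAS (n ≈ 977,323 with 47,309 cases), but
nothing in the code is specific to those traits: any conforming
summary-statistic tables work.

## The model

For variant $j$, let $\hat\beta_{Xj}, \sigma_{Xj}$ be the estimated
per-allele effect on the exposure and its standard error, and
$\hat\beta_{Yj}, \sigma_{Yj}$ the aligned effect on the outcome. Under the
instrumental-variable assumptions (association with the exposure, no
confounding of the variant–outcome relation, no effect on the outcome except
through the exposure), each variant provides a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$.

The primary estimator is inverse-variance weighting (IVW): weighted least
squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with
weights $1/\sigma_{Yj}^2$, which is the fixed-effect meta-analysis of the
Wald ratios. MR-Egger adds a free intercept (average directional pleiotropy
under the InSiDE assumption), the weighted median is consistent if variants
carrying half the weight are valid, and the mode estimators (weighted and
simple) take the argmax of a normal-kernel density over the ratios.

Mediation uses the two-step product-of-coefficients decomposition. With
$\beta_A$ the exposure-to-mediator IVW estimate, $\beta_B$ the
mediator-to-outcome IVW estimate (from the mediator's own instruments), and
$\theta_T$ the total exposure-to-outcome IVW estimate:

- mediated effect $= \beta_A \beta_B$, with first-order delta (Sobel)
  variance $\beta_B^2\sigma_A^2 + \beta_A^2\sigma_B^2$;
- direct effect $= \theta_T - \beta_A\beta_B$ (the identity
  direct + mediated = total holds exactly in every output);
- mediated proportion $= 100\,\beta_A\beta_B/\theta_T$ percent, with the
  delta variance of a ratio of independent estimates.

The two legs come from different GWAS samples, so their independence — which
both delta formulas assume — is plausible by design; it is an assumption,
not a theorem, and is stated as such in the documentation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `iv_pvalue` | 1e-5 | exposure-association screen for instruments; the conventional relaxed threshold for molecular traits, where genome-wide 5e-8 leaves too few instruments |
| `clump_r2` | 0.001 | maximum pairwise squared correlation between retained instruments |
| `clump_kb` | 10000 | half-window (kb) around the index variant for clumping |
| `min_f` | 10 | weak-instrument cutoff on per-SNP $F = (\hat\beta/\sigma)^2$ |
| `palindrome_policy` | drop | strand-ambiguous A/T and C/G variants are discarded; `infer_by_eaf` keeps them when both allele frequencies are outside [0.42, 0.58] |
| `ivw_variant` | multiplicative_random | residual scale $\max(1,\sqrt{Q/(n-1)})$ inflates the IVW SE under heterogeneity, never deflating below the fixed-effect SE |
| `screen_alpha` | 0.01 | p-value at which screened exposures/mediators are carried forward |
| `fdr_alpha` | 0.05 | Benjamini–Hochberg threshold of the "causal" evidence tier |
| `leg_alpha` | 0.05 | threshold for the exposure-to-mediator leg |
| `n_boot` | 1000 | parametric-bootstrap replicates behind median/mode SEs |
| `presso_nsim` | 1000 | parametric simulations behind the pleiotropy residual-sum test |

Evidence tiering follows a three-level rule: FDR < 0.05 is reported as
causal; FDR ≥ 0.05 with p < 0.05 as suggestive; p ≥ 0.05 as no evidence.
`screen_alpha` and `fdr_alpha` are deliberately separate knobs: screening
reports associations at p < 0.01 while the tier label is an FDR statement,
and the two families (exposures, mediators) are adjusted separately because
they are separate screening experiments. The exposure-to-mediator legs are
tested at a plain `leg_alpha` = 0.05 without multiplicity adjustment — a
choice the scan records, made because these legs are confirmatory tests on
the few screen survivors rather than a family-wide search.

## Sensitivity diagnostics

Cochran's $Q$ uses the no-measurement-error (NOME) ratio weights
$\hat\beta_{Xj}^2/\sigma_{Yj}^2$, making it algebraically identical to the
weighted residual sum of squares of the IVW regression — so
$Q = (n-1)\,s^2$ for the multiplicative residual scale $s$ before its floor
at 1, an internal consistency the tests assert. The Egger intercept test
uses $t_{n-2}$. Leave-one-out refits the IVW estimator $n$ times and flags
fits whose interval overturns the full-set sign conclusion.

The pleiotropy residual-sum (MR-PRESSO-style) diagnostic is re-implemented
from its published algorithm: the observed weighted RSS around leave-one-out
IVW predictions is compared against `presso_nsim` parametric simulations
under no pleiotropy (global test, empirical p floored at
$1/(\text{nsim}+1)$); per-variant contributions against their simulated
distributions with Bonferroni adjustment (outlier test); and the
outlier-corrected IVW slope against removals of equally many random variants
(distortion test). Outlier-corrected estimates are surfaced but never
silently substituted for the headline estimates, since correction changes
the estimand and should be an analyst decision.

## The synthetic-data generator

`simulate_study()` / `simulate_scan_study()` generate summary statistics
directly, without individual-level genotypes. Per-variant true effects on
the exposure are drawn from $N(0, \gamma_{sd}^2)$ truncated to
$|\gamma| \ge \gamma_{sd}$ (instruments that survive an F filter are strong
by construction in real pipelines too); mediator effects are
$\gamma_j\beta_A$ plus the mediator's own instruments $\delta_k$; outcome
effects are $\gamma_j\theta_T + \delta_k\beta_B + \alpha_j$ with $\alpha_j$
the optional pleiotropy term (balanced: zero-mean; directional: nonzero
mean, independent of $\gamma_j$, so InSiDE holds). Observed effects add
$N(0, se^2)$ noise with $se = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$,
further divided by $\sqrt{cf(1-cf)}$ for the binary outcome — the standard
large-sample scale for standardized traits.

Default study conditions mirror the motivating cohorts: sample sizes 3,757 /
8,299 / 977,323 with case fraction 47,309/977,323, 30 instruments per trait,
$\theta_T = 0.04$ log-OR per SD (odds ratios near 1.04, typical of
immune-trait effects on heart failure), $\beta_A = 0.2$ SD,
$\beta_B = 0.033$ log-OR per SD, hence a true mediated proportion of 16.5%,
within the 10–20% range such studies report. These were fixed once as the
package's reference conditions.

The mediator receives its own instrument set because the exposure's
instruments reach the outcome through the direct path and are therefore
pleiotropic for the mediator-to-outcome leg; a generator without
mediator-specific instruments could not identify $\beta_B$ by any
summary-data method.

What the generator does *not* emulate: realistic LD (blocks are synthetic
"echo" variants at a single $r^2$; the panel covers instrument-candidate
variants, as clumping reference extracts do), sample overlap between
cohorts, winner's curse beyond the implicit selection at the screen
threshold, population stratification, and allele-frequency differences
between cohorts. Passing recovery tests therefore demonstrates correctness
of the estimators and plumbing under the stated model, not robustness to
those real-data pathologies.

## Numerical choices

- Per-SNP instrument strength is $F = (\hat\beta/\sigma)^2$, the standard
  large-sample approximation; an allele-frequency-based $R^2$ with
  $F = R^2(n-2)/(1-R^2)$ is available (`instrument_r2()`) as the power
  calculator's input.
- Clumping ties on p-value break by smaller position then lexicographic
  variant id, making results independent of input row order.
- The weighted median interpolates centred cumulative weights at 0.5; mode
  estimators use a modified Silverman bandwidth
  $0.9\,\mathrm{mad}(\hat\theta_j)\,n^{-1/5}$ (falling back to the SD when
  the MAD degenerates) over a 4,096-point grid spanning the ratios ±3
  bandwidths.
- Bootstrap SEs (median/mode) resample each $\hat\beta$ from a normal with
  its reported SE; every stochastic routine takes an explicit seed recorded
  in its output, and pipeline stages derive their seeds from one root seed,
  so a single integer reproduces an entire run byte-for-byte.
- Degenerate inputs: a single instrument falls back to the Wald ratio;
  estimators refuse (as structured "insufficient instruments" conditions)
  below their minimum counts (Egger/median/mode 3, the residual-sum test 4);
  the pipeline converts these to skip records rather than errors.
- Empirical p-values are floored at $1/(\text{nsim}+1)$, never exactly zero.
- Harmonization treats variant ids as opaque join keys (no genome-build
  liftover); indels and multi-allelic records are rejected at read time.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen to keep the full suite in
minutes while leaving Monte-Carlo error well inside the asserted bands:
oracle-equivalence checks on 100 random instrument sets (coefficients to
1e-10), clumping equivalence on 200 random 20-variant panels, Q calibration
on 1,000 null replicates, Egger-intercept calibration on 2,000 replicates of
50 variants, delta-CI coverage on 5,000 replicates, and end-to-end recovery
on 500 replicate studies of 30 instruments. A consortium-scale screen (731
exposures × 1,400 mediators) is a straightforward loop over the same
primitives.

## Known limitations

- First-order delta intervals for the mediated effect and proportion are
  approximate; coverage is validated at 93–97% under strong instruments but
  degrades when the total effect is imprecise or near zero (the ratio's
  delta variance is then unreliable). Opposite-sign mediated and total
  effects are flagged `inconsistent` rather than reported as absolute
  values.
- The reverse-direction mode is a plain exposure/outcome swap under the same
  thresholds; no reverse-specific instrument strategy is attempted.
- Instruments absent from the outcome GWAS are dropped (no proxy lookup).
- The NOME approximation in $Q$ and the IVW weights ignores exposure-side
  noise; with instruments at $F \ge 10$ the induced attenuation is below
  ~3% and inside the validated coverage bands, but very weak instruments
  would need different weighting entirely.
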