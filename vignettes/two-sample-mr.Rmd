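---
title: "Two-sample Mendelian randomization with mrkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational GWAS data. In the two-sample setting the per-variant
associations come from separate studies: for instrument $j$ we observe an
exposure effect $\hat\beta_{Xj}$ with standard error
$\sigma_{Xj}$ and an outcome effect $\hat\beta_{Yj}$ (log odds for a
binary outcome) with standard error $\sigma_{Yj}$. Under the
instrumental-variable assumptions — the variant is associated with the
exposure, independent of confounders, and affects the outcome only
through the exposure — each variant provides a Wald ratio estimate
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ of the causal effect
$\theta$.

`mrkit` implements the standard estimator battery on a harmonized set of
such pairs:

* **IVW** — the inverse-variance weighted mean of the Wald ratios,
  $\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum_j w_j
  \hat\beta_{Xj}^2$ with $w_j = 1/\sigma_{Yj}^2$; algebraically a
  weighted regression of outcome on exposure effects through the origin.
  The fixed-effect standard error is
  $(\sum_j \hat\beta_{Xj}^2/\sigma_{Yj}^2)^{-1/2}$; the multiplicative
  random-effects variant inflates it by $\sqrt{Q/(k-1)}$ when Cochran's
  $Q$ exceeds its degrees of freedom. Both share the point estimate.
* **MR-Egger** — the same weighted regression with a free intercept,
  after orienting every instrument so $\hat\beta_{Xj} \ge 0$. The slope
  is a causal estimate robust to directional pleiotropy under the InSIDE
  assumption (instrument strength independent of direct effects); the
  intercept estimates the average direct effect. Inference is $t$-based
  with $k-2$ degrees of freedom, with the residual standard deviation
  floored at 1 so under-dispersion never shrinks the fixed-effect SE.
* **Weighted median** — the weighted 50th percentile of the ordered
  ratios with weights $\propto \hat\beta_{Xj}^2/\sigma_{Yj}^2$, obtained
  by linear interpolation of the cumulative weight midpoints
  $S_j = \sum_{i \le j} w_i - w_j/2$ at $S = 0.5$; consistent when valid
  instruments carry at least half the weight.
* **Simple and weighted mode** — the argmax of a normal-kernel density
  of the ratios (uniform or inverse-variance weights), bandwidth
  $\varphi \cdot 0.9 \min(\mathrm{sd}, 1.4826\,\mathrm{MAD})k^{-1/5}$
  on a 512-point grid spanning the ratio range extended by three
  bandwidths; consistent when the largest homogeneous cluster of
  instruments is valid. When the ratios tie exactly the MAD — and hence
  the bandwidth — collapses to zero, and the estimator falls back to the
  weighted median of the ratios, which equals the tied cluster's value.

Median and mode standard errors come from a parametric bootstrap:
$\hat\beta_{Xj}^* \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$,
$\hat\beta_{Yj}^* \sim N(\hat\beta_{Yj}, \sigma_{Yj}^2)$, re-estimating
on each of `n_boot` draws (default 1000, seeded — point estimates never
depend on the bootstrap). Confidence intervals use the normal multiplier
1.959964, except MR-Egger's $t$ quantile, so all CI fields are
bit-stable. Wald-ratio SEs use the first-order delta method
$\sigma_{Yj}/|\hat\beta_{Xj}|$; exposure-side uncertainty enters through
the bootstrap only.

## Instrument processing

`select_instruments()` keeps variants below the genome-wide threshold
$5\times10^{-8}$ (strict inequality). `clump()` prunes linkage
disequilibrium greedily: candidates are ranked by ascending p (ties
broken lexicographically by rsID for determinism), the best remaining
variant indexes a clump, and any remaining same-chromosome variant
within 10,000 kb *and* with $r^2 \ge 0.001$ against it is removed. Both
gates must fire; distance is $|pos_1-pos_2| \le$ window in base pairs.
LD is supplied by the user as a square matrix — the package never
estimates it from genotypes.

`harmonize_pair()` aligns outcome to exposure effect alleles: identical
pairs pass, swapped pairs negate the outcome beta (and reflect the
allele frequency), strand complements are complemented first.
Palindromic variants (A/T, C/G) are excluded outright by default rather
than resolved by allele frequency, since frequency resolution is
unreliable near 0.5 and frequencies are often unavailable. Instruments
missing from the outcome dataset are recorded as exclusions — no proxy
search is attempted. Records carrying a `pre_aligned` flag (used by the
bundled instrument table, which reports effects already aligned to a
common allele but no allele labels) bypass allele logic unchanged.

## Diagnostics and power

Cochran's $Q = \sum_j ((\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})/
\sigma_{Yj})^2$ against $\chi^2_{k-1}$ tests ratio homogeneity, with the
fixed-effect IVW estimate as reference. `leave_one_out()` recomputes IVW
dropping each instrument in turn. Instrument strength uses
$F = R^2(n-k-1)/(k(1-R^2))$ with the weak-instrument flag at $F < 10$;
because allele frequencies are not always available, $R^2$ is estimated
from summary data as $\sum_j t_j^2/(t_j^2 + n - 2)$ with
$t_j = \hat\beta_{Xj}/\sigma_{Xj}$ — an approximation that assumes
independent instruments, and is labelled as such in reports.

Binary-outcome power uses the symmetric asymptotic approximation: the
test statistic non-centrality is $\ln(\mathrm{OR})\sqrt{nR^2K(1-K)}$
with $K$ the case fraction, giving
$\mathrm{power} = \Phi(-z_{1-\alpha/2}+z) + \Phi(-z_{1-\alpha/2}-z)$.
At OR = 1 this returns exactly $\alpha$, and detectable-OR bounds found
by bisection (tolerance $10^{-6}$ on power) are reciprocal on the log
scale. Web calculators in common use apply an asymmetric attenuation
formula whose inputs are not always recoverable; this closed form is
reproducible and monotone, which the tests verify, but its bounds need
not match such tools exactly.

## The synthetic-data generator

`simulate_summary_stats()` draws summary statistics directly from their
asymptotic sampling distributions: true exposure effects
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$ truncated away from zero
at $|\gamma_j| \ge \sigma_\gamma/10$ (unstable Wald denominators would
otherwise dominate small-sample tests), direct effects $\alpha_j$ that
are zero (`none`), centred (`balanced`) or shifted (`directional`), and
observed effects $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_X^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_Y^2)$. Defaults
($k = 50$, $\mu_\gamma = 0.07$, $\sigma_\gamma = 0.03$,
$\sigma_X = 0.008$, $\sigma_Y = 0.03$, $n$ = 44,147 / 79,429) mirror the
scale of a homocysteine-sized quantitative-trait GWAS paired with a
large case-control outcome GWAS. The generator emulates exactly the
model the estimators assume — independent instruments, normal sampling
noise, no LD, no winner's curse, no sample overlap — so passing
operating-characteristic tests demonstrates correctness of the
estimators under their own assumptions, not robustness to the ways real
GWAS data violate them.

`run_simulation_study()` derives per-replicate seeds deterministically
from the config seed and reports mean estimate, empirical SE, bias,
95%-CI coverage and rejection rate per method. Two scenario-design
points deserve emphasis, because they reflect estimator assumptions
rather than implementation choices:

* The Egger intercept estimates mean directional pleiotropy only when
  (a) exposure effects are measured essentially without error (the NOME
  assumption — otherwise regression dilution leaks part of
  $\theta\bar\gamma$ into the intercept), and (b) the $\hat\beta_X \ge 0$
  orientation is stable. If true effects straddle zero, the occasional
  sign flip negates that instrument's direct effect and such points sit
  at high leverage near the intercept; with
  $\gamma \sim N(0.07, 0.03^2)$ roughly 1% of instruments flip, biasing
  the recovered intercept by about $-0.001$ to $-0.002$. The
  pleiotropy-recovery tests therefore simulate strongly measured,
  same-signed instruments ($\sigma_X = 0.002$,
  $\gamma \sim N(0.1, 0.02^2)$), which satisfies both conditions.
* Monte-Carlo checks of size and coverage use 500 replicates and are
  asserted within the binomial 95% margin of the nominal level; point
  recovery within four Monte-Carlo standard errors of the mean.

## The bundled worked example

`load_table1_fixture()` embeds, as code constants, an eleven-variant
instrument set for plasma homocysteine (GWAS of 44,147 European-ancestry
subjects) paired with three intracranial-aneurysm outcome datasets
(79,429 individuals; 7,495 IA, 2,070 unruptured-IA and 5,140 ruptured
aSAH cases). Two instruments are unavailable in the unruptured dataset
and have no proxies, leaving 9 of 11 there; `run_table1_study()` runs
the full pipeline on all three outcomes:

```{r study, eval = FALSE}
report <- run_table1_study(seed = 1)
estimates_table(report)
```

All fifteen method-by-outcome p-values exceed 0.05 — a null result. The
fixed-effect IVW odds ratios computed from the table as published are
1.188 (IA), 1.170 (aSAH) and 1.201 (unruptured IA). These sit above the
originally reported 1.124/1.104/1.126 by up to 0.07 on the log-OR scale:
the published per-variant coefficients are rounded to two or three
decimals and carry no allele labels or frequencies, so the exact
harmonized inputs behind the original estimates are not recoverable.
The direction, the confidence-interval overlap and the null conclusion
are reproduced; the residual gap is a documented property of the
published table, not adjustable behaviour of this package. For the same
reason the published F-statistics (100.340 and 47.203) cannot be
re-derived — the summary-data $R^2$ here gives 108.8 and 62.6 — and the
formula is instead anchored by exact algebraic checks.

## Numerical and degenerate-input policy

Zero exposure effect makes the Wald ratio undefined (error). One
instrument degrades IVW to the Wald ratio with a warning; Egger, median
and mode require three. Tied ratios collapse the mode bandwidth
(fallback above). Clumping ties on p break lexicographically.
Bootstraps and simulations are seeded everywhere; identical seeds give
bit-identical datasets, estimates and serialized reports. Report JSON
serializes numbers at full precision.

## Limitations

No MR-PRESSO or multivariable MR, no Steiger filtering, no proxy-variant
search, no LD estimation from reference panels, no allele-frequency
resolution of palindromic variants, no individual-level simulation.
These are deliberate boundaries; the estimator surface covers the five
standard methods and their conventional diagnostics.
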