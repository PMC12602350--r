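---
title: "Drug-target Mendelian randomization with TargetMR: models, parameters, design"
author: "TargetMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with TargetMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TargetMR)
```

# The scientific problem

Agonists of the incretin receptors GLP1R and GIPR lower body-mass index
and glycated hemoglobin (HbA1c). Whether that pharmacology also changes
behavioural and hepatic outcomes — alcohol misuse, food preference,
fatty liver — cannot be read off short randomized trials, but genetics
offers a proxy: variants *within the receptor loci* that associate with
the biomarker act, in effect, as a lifelong randomized micro-dose of
receptor modulation. Drug-target Mendelian randomization (MR) uses such
cis variants as instrumental variables in the standard two-sample
summary-statistics framework: per-SNP exposure effects
$(\hat\beta_{Xj}, \sigma_{Xj})$ from a biomarker GWAS, outcome effects
$(\hat\beta_{Yj}, \sigma_{Yj})$ from an independent cohort, and a
causal effect $\theta$ estimated from their ratios.

TargetMR implements the full pipeline — instrument construction,
estimation, colocalization, mediation, carrier prevalence and
orchestration — together with a synthetic-data generator that makes
every stage testable against known ground truth.

# Cis-instrument construction

**Window.** A target locus is a gene interval on GRCh37 with a flanking
window (default 500 kb each side); the window is closed on both ends and
coordinates are 1-based, so GLP1R at 6:39,016,574–39,055,519 yields the
retained interval [38,516,574, 39,555,519].

**Threshold cascade.** SNPs are filtered at genome-wide significance
(P < 5×10⁻⁸). When a locus yields nothing at that level — common for
cis windows of secondary biomarkers — the selection falls back to a
relaxed 5×10⁻⁶, and the level actually used is recorded on the
instrument set. The cascade is generic: any strictly increasing
threshold sequence is accepted, and the fallback applies per locus.

**Clumping.** Independence is enforced by greedy clumping at
r² < 0.1 against a user-supplied LD matrix: SNPs are ordered by
p-value, ties broken by |z| descending and then lexicographic id so the
selection is reproducible, and each kept SNP removes all remaining SNPs
in LD with it. On small instances the greedy result coincides with the
lexicographically best admissible subset in p-order, which the test
suite verifies by exhaustive enumeration.

**Dual targets.** Multi-locus instruments (e.g. a combined GIPR/GLP1R
set) are built by clumping each locus separately and concatenating —
cross-chromosome LD is not modelled — with set-level diagnostics
recomputed on the union. Whether one should clump across the union
window instead is genuinely open; per-locus clumping was chosen because
combined instruments are defined as unions of already-validated
single-locus sets.

**Orientation.** Every SNP is re-expressed on the allele with a
positive exposure effect (labels swapped, frequency complemented, flip
recorded); applying the operation twice equals applying it once. The
*reporting* direction is a property of the study: under
`direction = "lowering"` the orchestrator negates causal estimates at
reporting time so they read *per 1 SD biomarker decrease*, matching how
agonist therapy moves the biomarker. A SNP with an exactly zero effect
cannot be oriented and is left in place with a warning.

**Strength.** Per-SNP $F_j = (\hat\beta_{Xj}/\sigma_{Xj})^2$ and
variance explained $r^2_j = F_j/(F_j + n - 2)$; the set-level R² sums
the per-SNP values, treating clumped SNPs as independent — the standard
approximation when only summary LD is available. Any $F_j < 10$ raises
a weak-instrument flag. Sensitivity instruments defined by external
biology (missense SNPs, eQTL lists) bypass the P/LD cascade via
`instrumentFromSnps()` but still undergo harmonization, orientation and
diagnostics.

# Harmonization

Outcome records are aligned to the exposure's effect allele: swapped
labels negate the outcome beta and complement its frequency;
opposite-strand reports are complemented first. Palindromic SNPs (A/T,
C/G) cannot be resolved from labels; the default policy aligns them by
allele frequency when both traits have $\min(f, 1-f) < 0.42$ — the
conventional ambiguity threshold — and drops them otherwise, or when
the outcome frequency is missing. The alternatives (`"drop"`,
`"keep"`) are available because published analyses differ in dialect
and no single convention is authoritative. Harmonization is idempotent,
and irreconcilable allele sets are dropped with an explicit reason
rather than silently.

# Estimators

For a single-SNP instrument the Wald ratio
$\hat\theta = \hat\beta_Y/\hat\beta_X$ with first-order standard error
$\sigma_Y/|\hat\beta_X|$ is the primary estimator; from two SNPs, IVW

$$\hat\theta_{IVW} =
  \frac{\sum_j \hat\beta_{Xj}\hat\beta_{Yj}\sigma_{Yj}^{-2}}
       {\sum_j \hat\beta_{Xj}^2 \sigma_{Yj}^{-2}},$$

the weighted regression of outcome on exposure effects through the
origin. The fixed-effect SE is
$(\sum_j \hat\beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}$; the multiplicative
random-effects model inflates it by $\max(1, \sqrt{Q/(n-1)})$. The
default uses fixed effects below 4 SNPs and random effects from 4 — a
pragmatic convention: with 2–3 SNPs the heterogeneity estimate is too
unstable to trust, with more it guards against overdispersion.
Confidence intervals use the normal 1.96 multiplier throughout, except
MR-Egger which uses t-quantiles at $n-2$ degrees of freedom.

From three SNPs the sensitivity suite runs:

* **MR-Egger** — weighted least squares with an unconstrained intercept
  (directional pleiotropy), SNPs first oriented to $\hat\beta_{Xj}\ge 0$
  by joint sign flips; SEs inflated by
  $\max(1,\sqrt{Q_{res}/(n-2)})$.
* **Weighted median** — per-SNP ratios weighted by
  $(\hat\beta_{Xj}/\sigma_{Yj})^2$, estimate interpolated at the 0.5
  cumulative-weight midpoint; consistent while valid instruments hold a
  weight majority.
* **Weighted mode** — Gaussian-kernel weighted density over the ratios
  with bandwidth $h = \phi\, s\, n^{-1/5}$, where $s$ is the
  MAD-based robust scale (constant 1.4826, falling back to the SD when
  the MAD is zero) and $\phi$ defaults to 1; the estimate is the
  density argmax on a 512-point grid. When all ratios coincide their
  common value is returned exactly. The bandwidth factor is exposed
  because the mode is the one estimator with a genuine smoothing
  parameter; doubling it should move the estimate smoothly, which the
  tests check.
* **MR-LASSO** — $\hat\beta_{Yj} = \alpha_j + \theta\hat\beta_{Xj}$
  with $\lambda\sum_j|\alpha_j|$ penalization. Each $\alpha_j$ enters a
  single observation, so coordinate descent reduces to exact per-SNP
  soft-thresholds and converges in a handful of sweeps. The path runs
  over 50 log-spaced $\lambda$ values from $\lambda_{max}$ (all
  intercepts zero) down to $0.001\lambda_{max}$, and the reported model
  is the largest valid set whose post-selection Q stays below the
  chi-square 0.05 critical value; the final estimate is fixed-effect
  IVW on that set. When no grid point satisfies the rule the
  smallest-$\lambda$ valid set with at least two SNPs is used and
  flagged in the notes — a deliberate fail-soft, since the alternative
  (erroring) would discard the estimator exactly when heterogeneity is
  most interesting.

Median and mode SEs come from a parametric bootstrap (1000 resamples of
the per-SNP effects from their normal sampling distributions, seeded
and recorded in the result notes); 1000 keeps Monte-Carlo error on the
SE near 2% while staying fast. All estimators return $\theta$ exactly
on noise-free all-valid data — the no-noise equivalence the test suite
asserts.

Binary outcomes are analysed on the log-odds scale throughout and
exponentiated to odds ratios only at reporting time, so multi-method
comparisons are always on the additive scale.

# Diagnostics

**Cochran's Q** over per-SNP ratios with weights
$(\hat\beta_{Xj}/\sigma_{Yj})^2$, referred to chi-square with $n-1$
degrees of freedom. Under resampling of valid-instrument outcomes it is
chi-square distributed, which the suite checks with a
Kolmogorov–Smirnov test at 5000 replicates.

**Steiger directionality** compares instrument variance explained in
exposure versus outcome, recovering per-SNP $r^2$ from the reported
p-value and sample size via the t-distribution
($r^2 = t^2/(t^2+n-2)$, summed over SNPs) and comparing Fisher-z
transformed correlations with the two sample sizes. Forward causation
should explain more variance in the exposure. For case-control
outcomes the liability-scale conversion is out of scope; the result is
flagged not-computed rather than silently wrong.

# Colocalization

A significant MR estimate can still be confounded by LD between
distinct causal variants; colocalization tests the shared-variant
explanation. Per SNP, the Wakefield approximate Bayes factor uses a
normal prior on the true effect with variance $W$: with
$z = \hat\beta/\sigma$, $V = \sigma^2$ and shrinkage $r = W/(W+V)$,

$$\log ABF = \tfrac12\left(\log(1-r) + r z^2\right).$$

The prior effect SD defaults to $0.15\,sd_Y$ for quantitative traits
and 0.2 on the log-odds scale for case-control traits — the cited
method's conventions. When $sd_Y$ is unknown it is estimated from the
locus itself (the reciprocal slope of $1/\sigma^2$ regressed through
the origin on $2f(1-f)n$) and flagged; a user-supplied value always
wins.

Posteriors for the five single-causal-variant hypotheses (H0 nothing,
H1/H2 one trait only, H3 two distinct variants, H4 one shared variant)
are assembled entirely in log space with log-sum-exp and a guarded
log-difference, and match naive linear-space enumeration to 10⁻¹⁰ on
loci up to 20 SNPs (a brute-force oracle in the tests); they sum to one
within 10⁻¹². A single-SNP locus has an empty off-diagonal sum, hence
$PP_{H3}=0$ exactly. Priors default to $p_1=p_2=10^{-4}$,
$p_{12}=10^{-5}$. Both $PP_{H4}$ and the conditional ratio
$PP_{H4}/(PP_{H3}+PP_{H4})$ — informative when the outcome signal is
weak — are always reported; the 0.60 shared-variant threshold is a
label on the output, never a filter. In the orchestrator,
colocalization runs for pairs whose primary MR p-value is below 0.05
(configurable), mirroring standard practice of probing only nominally
significant signals.

# Mediation

Two-step MR decomposes a total effect into the component through a
mediator: indirect $=\beta_1\beta_2$ from independent
exposure-to-mediator and mediator-to-outcome MR fits, with the Sobel
standard error
$\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$ justified by the
two-sample independence of the inputs. The proportion mediated
indirect/total is an unstable ratio; it is suppressed (reported missing
with a reason) on sign conflict between indirect and total, or when
$|total| < 10\,se_{total}$. That z-threshold of 10 is deliberately
conservative — it only reports proportions when the denominator is
essentially noise-free — and is configurable (`zTotalMin`) for studies
content with, say, $|z|>4$. Step-2 instruments are genome-wide
instruments for the mediator supplied as their own set; no adjustment
for the exposure is made (univariable two-step), so the decomposition
assumes no exposure–mediator interaction.

# Carrier prevalence

Under Hardy–Weinberg equilibrium the probability of carrying at least
one activation allele is $P_{carrier} = 1-(1-f)^2$ per SNP and
$P_{locus} = 1-\prod_i(1-f_i)^2$ across independent instrument SNPs,
averaged across instrument sets into an ancestry-level summary. The
independence assumption is exactly the clumping guarantee; when an LD
matrix is supplied, residual within-set LD above the clumping threshold
triggers a warning. Note that for a single SNP the carrier probability
exceeds the allele frequency itself (f = 0.46 gives
$P_{locus} = 0.71$), so quoting the frequency as a "percent of
carriers" understates carriage; published tables occasionally conflate
the two, and the package always reports the Hardy–Weinberg value while
storing full precision behind the two-decimal presentation.

# The synthetic generator

`simulateTwoSample()` draws effect-allele frequencies uniformly on
[0.05, 0.95], builds a block-constant LD correlation matrix (positive
definite by construction for $\rho<1$; an AR(1) option exists for
colocalization realism), places causal effects and forms marginal
effects $R\beta_{causal}$, then samples exposure and outcome estimates
from independent multivariate normals — the defining two-sample,
non-overlapping-cohort assumption. Sampling SEs follow the
standardized-trait form $1/\sqrt{2nf(1-f)}$, with
$1/\sqrt{2ns(1-s)f(1-f)}$ on the log-odds scale for case-control
outcomes (an approximation adequate for method testing, not a
likelihood-level binary-trait simulation). Pleiotropy assigns direct
outcome effects to a configurable fraction of causal SNPs, balanced or
directional. Defaults (30 SNPs, $n_X = 3\times10^5$,
$n_Y = 5\times10^5$, causal effects around 0.02 SD) put instrument
F-statistics in the tens-to-hundreds typical of published cis
instruments.

What the generator does **not** emulate: real human LD maps, realistic
allele-frequency spectra, sample overlap between cohorts, winner's
curse from discovery-based instrument selection, and population
stratification. Passing tests therefore demonstrate correctness of the
estimators and pipeline under the stated model, not robustness to every
pathology of real GWAS data.

Scenario generators add colocalization configurations H0–H4 (H3 draws
its second causal variant from a different LD block, r² below 0.04 by
default) and a three-pair mediation design with configurable
$\beta_1$, $\beta_2$ and direct effect. All generation is seeded once
per call, the seed is recorded in the emitted truth object, and truth
round-trips through JSON at 17 significant digits, i.e. exactly.

# Validation scale

The test suite exercises the stack at sizes chosen to bound Monte-Carlo
error well inside the asserted tolerances: IVW confidence-interval
coverage over 2000 replicate studies of 10 independent SNPs (expected
in [0.93, 0.97]); colocalization scenario recovery over 200 replicates
each of H4 and H3 at 50-SNP loci; the Q null distribution over 5000
replicates; Steiger direction accuracy over 200 forward-causal studies;
mediation SE against 10⁵ Monte-Carlo draws. The full synthetic study
(two targets × two biomarkers × two sources × three outcomes) must
reproduce its report byte-for-byte under a fixed seed.

# Numerical and degenerate-input choices

* Colocalization is computed in log space; the log-difference for H3
  tolerates sub-epsilon inversions from floating-point summation and
  returns an exact zero posterior rather than failing.
* Weighted-mode degeneracy (all ratios equal) returns the common ratio;
  a zero MAD falls back to the SD before giving up.
* Clumping tie-breaks (p, then |z|, then id) make instrument selection
  a pure function of its inputs.
* `mediate()` treats a zero step coefficient as proportion 0, a zero
  total as missing, and reports the suppression reason explicitly.
* Rows failing validation on read are dropped and counted, never
  repaired; an empty table after filtering is an error.
* The p-versus-z consistency check on read warns at a relative
  tolerance of 10⁻³ on $-\log_{10}p$ — published tables round, so this
  is a tripwire for unit errors, not a gate.

# Limitations

Single-causal-variant colocalization cannot represent allelic series;
multivariable MR, CAUSE/MR-PRESSO-style outlier modelling, liability-scale
Steiger for binary outcomes, LD estimation from genotypes and genome-build
liftover are out of scope. LD matrices are inputs: the package neither
manages reference panels nor transfers LD across ancestries — multi-ancestry
analyses are separate configurations with ancestry-matched inputs.
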