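---
title: "Two-sample MR screening and two-step mediation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR screening and two-step mediation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Observational associations between immune cell phenotypes, circulating
metabolites and disease outcomes such as hepatocellular carcinoma are
confounded by lifestyle, environment and reverse causation. Two-sample
Mendelian randomization (MR) sidesteps part of this problem by using
genetic variants as instrumental variables: because alleles are assigned at
conception, a variant that raises an exposure trait provides a natural
experiment for the exposure's downstream effect. `mrmediate` implements the
full summary-statistic workflow — instrument selection, allele
harmonization, five causal estimators, a sensitivity battery, reverse-MR
filtering, FDR evidence tiers, and two-step mediation — together with a
seeded synthetic-data generator with known causal structure, so that every
stage can be validated against ground truth without access to the original
GWAS cohorts.

## Model and estimators

For instrument $j$ the exposure GWAS supplies $(\hat\beta_{Xj},
\sigma_{Xj})$ and the outcome GWAS $(\hat\beta_{Yj}, \sigma_{Yj})$, on the
log-odds scale for binary outcomes. Under the instrumental-variable
assumptions each Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
causal effect $\beta$.

* **IVW**: $\hat\beta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum_j
  w_j \hat\beta_{Xj}^2$ with $w_j = \sigma_{Yj}^{-2}$ — the slope of a
  zero-intercept weighted regression of outcome on exposure effects. The
  default variance model is multiplicative random effects: the
  fixed-effect standard error is inflated by $\max(1, \sqrt{Q/(k-1)})$,
  where $Q$ is Cochran's statistic at the IVW estimate. This is the
  mainstream choice for trait panels, robust to balanced heterogeneity;
  the fixed-effect model is available by argument.
* **MR-Egger**: the same regression with a free intercept, after orienting
  every instrument so $\hat\beta_{Xj} \ge 0$. The intercept estimates the
  mean directional pleiotropic effect; standard errors carry the analogous
  $\max(1, \sqrt{Q'/(k-2)})$ inflation. Orientation to the
  exposure-increasing allele is the convention under which "directional"
  pleiotropy is identifiable at all — under the opposite sign convention
  for half the instruments, any constant direct effect would cancel.
* **Weighted median**: the cumulative-weight interpolation at 0.5 over
  sorted ratios with weights $\hat\beta_{Xj}^2/\sigma_{Yj}^2$, consistent
  while valid instruments carry a majority of weight. Its standard error
  comes from a seeded parametric bootstrap (default 1,000 replicates)
  redrawing both $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from their reported
  standard errors.
* **Weighted and simple mode**: the argmax of a normal-kernel density of
  the ratios with bandwidth $\varphi \cdot 0.9\,\min(\mathrm{sd},
  \mathrm{IQR}/1.349)\,k^{-1/5}$ ($\varphi = 1$ by default), evaluated on
  a fixed grid of 10,000 points spanning the ratio mean $\pm$ 5 SD. The
  deterministic grid makes the argmax reproducible without a seed; the
  standard error is again a seeded parametric bootstrap. When all ratios
  coincide the bandwidth degenerates and the common ratio is returned with
  a zero standard error and a warning.

All p-values are two-sided normal; no small-sample t-correction is
applied anywhere, which keeps estimates, intervals and p-values mutually
consistent under $se = (\ln\mathrm{hi} - \ln\mathrm{lo})/(2 z_{0.975})$ —
the identity the worked-example checks rely on.

## Instrument selection

Selection follows five steps, all with strict inequalities: (1) exposure
association at $p < 5\times10^{-5}$ (the conventional panel-screen
threshold for modestly sized trait GWASs); (2) removal of variants
associated with the outcome at $p < 0.05$; (3) greedy distance-and-LD
clumping (smallest p first, window 10,000 kb, $r^2 < 0.001$ when an LD
provider is plugged in — the shipped implementation is distance-only,
which is exact for the generator's independent variants); (4) MR-PRESSO
outlier removal, applied by the pipeline between selection and final
estimation; (5) per-SNP F-statistic $(\hat\beta/\sigma)^2 \ge 10$.

Two points deserve comment. First, the clumping window: one convention in
the applied literature states the window in base pairs ("10,000 bp"), but
a 10,000 **kb** window is the standard for metabolite and immune-trait
panels; the window is configurable and defaults to 10,000 kb. Second, the
outcome-association filter (step 2) truncates the outcome-effect
distribution of retained instruments. With real panels the per-SNP outcome
effects are tiny and the filter is nearly inert, but at simulation scale —
few instruments with large per-SNP effects — it visibly distorts both null
calibration (rejection below nominal) and recovery of nonzero effects
(true instruments stripped). Calibration and recovery studies therefore
disable it (`instrument_config(outcome_p_threshold = 0)`); the screening
pipeline keeps it on by default, as the procedure prescribes.

Harmonization aligns outcome to exposure effect alleles, resolving strand
flips by complement before comparison. Palindromic (A/T, C/G) variants
default to `drop_ambiguous`: removed when the exposure allele frequency
lies in 0.42–0.58, where the strand cannot be inferred from frequency.
This is the conservative common practice; the policy is configurable
(`drop_all`, `keep`) because published workflows frequently leave it
unstated.

## Sensitivity battery

Cochran's Q (IVW and Egger fits, df $k-1$ and $k-2$), the Egger intercept
test, leave-one-out IVW (flagging omissions that change the sign or leave
the full-set CI), and MR-PRESSO. The MR-PRESSO global test compares the
observed leave-one-out residual sum of squares against a parametric null
(default 1,000 simulations, seeded, rank-based p); per-SNP outliers are
called at a Bonferroni-adjusted 0.05 and removed before the corrected IVW
estimate. The distortion test of the original algorithm is out of scope.
Heterogeneity verdicts are reported, never silently acted on: the only
automatic exclusion in the pipeline is MR-PRESSO's, mirroring the
selection procedure, because published screens have retained
heterogeneous pairs at the reporting stage.

## Two-step mediation

For an exposure → mediator → outcome chain, `run_mediation` estimates
$\beta_1$ (exposure → mediator, instruments selected on the exposure),
$\beta_2$ (mediator → outcome, instruments selected on the mediator), and
the total effect (exposure → outcome, same instrument rules as the
screen). The mediated effect is $\beta_1\beta_2$ with delta-method
standard error $\sqrt{\beta_1^2 se_2^2 + \beta_2^2 se_1^2}$, a symmetric
normal CI and two-sided p — consistent with how published mediation
tables report symmetric intervals. The direct effect is total minus
mediated; the proportion is $100\,\beta_1\beta_2/\text{total}$, negative
under suppression (opposite signs, warned). The proportion CI uses the
first-order delta method treating mediated and total as independent —
their instrument sets differ, so first-order correlation through the
shared outcome sample is negligible — with a seeded parametric bootstrap
available as a cross-check. Proportion intervals are always reported
sorted (low, high).

One design decision matters for identification. A variant that reaches the
mediator *through the exposure* carries the exposure's direct path into
the mediator → outcome leg: its expected ratio is $(\theta_1\theta_2 +
\theta_d)/\theta_1$, not $\theta_2$. `run_mediation` therefore excludes
exposure-associated SNPs (exposure $p <$ threshold) from the mediator leg
by default. Without this exclusion — or with a mediator lacking
instruments of its own — the two-step decomposition degenerates toward a
100% proportion regardless of the truth.

## Multiplicity

IVW p-values are Benjamini–Hochberg adjusted within each screen (all
exposures against one outcome), matching per-screen practice; q < 0.05 is
labelled "strong", 0.05 ≤ q < 0.20 "suggestive", otherwise "none".
Candidates advance on IVW p < 0.05 with tiers reported alongside. The
reverse-MR filter then re-runs MR with the outcome as the instrumented
trait (same 5e-5 threshold on the outcome side) and removes candidates
with reverse p < 0.05.

## The synthetic generator

`simulate_triple` draws independent SNPs (MAF uniform on 0.05–0.5,
non-palindromic allele pairs, 22 chromosomes at 10,001 kb spacing so
distance clumping is a no-op) and a structural model: exposure effects
$\gamma_j \sim N(0, 0.15^2)$ on a `prop_causal` fraction (default 0.25 of
200 SNPs), mediator-specific effects $\delta_j$ on a disjoint fraction,
mediator $= \theta_{XM}\gamma + \delta$, outcome
$= (\theta_{XM}\theta_{MY} + \theta_{XY})\gamma + \theta_{MY}\delta +
\mathrm{sign}(\gamma)\,\alpha$ with optional pleiotropic shifts $\alpha$.
Pleiotropy is injected relative to the exposure-increasing allele —
otherwise allele-orientation symmetry makes its mean unidentifiable by
construction, and the Egger intercept would correctly estimate zero.
Sampling noise uses the standardized-trait standard error
$(2p(1-p)n)^{-1/2}$, inflated by $(\phi(1-\phi))^{-1/2}$ at a balanced
case fraction $\phi = 0.5$ for the binary outcome. Default sample sizes
(3,757 exposure; 8,299 mediator; 10,000 outcome) mirror the immune-trait
and metabolite GWAS scales that motivated the package; the default effect
scale 0.15 is what such sample sizes require for instruments to clear
$5\times10^{-5}$, matching the instrument counts (tens) seen in practice.
Defaults $\theta_{XM} = 0.4$, $\theta_{MY} = 0.3$, $\theta_{XY} = 0.1$
give a true mediated proportion of $100 \times 0.12/0.22 = 54.5\%$.

What the generator does **not** emulate: LD structure (the clump
interface accepts an external $r^2$ provider for that), realistic
allele-frequency spectra, sample overlap between GWASs, and winner's-curse
ascertainment of published hits. Passing recovery tests therefore
demonstrate correctness of the estimators and plumbing under the stated
model, not robustness to those real-data features.

## Validation problem sizes

The shipped checks use: 2,000 null replicates (60 SNPs each) for IVW and
Cochran's Q calibration and 800 for the MR-PRESSO global test at 500
simulations; 200 replicates at 50 SNPs and $n = 10{,}000$ for IVW bias
(true $\beta = 0.3$) and Egger-intercept recovery under 30% directional
pleiotropy (expected intercept $0.3 \times 0.05 = 0.015$); 100 replicates
for mediation-proportion recovery; and 20–50 random instances per
estimator for exact (1e-10) agreement with independent oracles (weighted
`lm` fits, brute-force scans, exhaustive grid evaluation). These sizes
keep Monte-Carlo error a fraction of the tolerance being checked.

## Known limitations

Univariable legs only: no multivariable MR, so direct effects are derived
by subtraction rather than joint modelling, and multiple mediators are
decomposed one at a time. No Steiger directionality filtering — the
reverse-MR screen plays that role at the trait level. The weighted-median
and mode bootstrap counts, the mode bandwidth multiplier, and the IVW
variance model are defaults chosen to match mainstream practice, not
values fixed by any external benchmark; all are arguments. Wald-ratio
standard errors are first-order (exposure uncertainty ignored), the usual
leading-order approximation, so single-instrument pairs inherit its
optimism. Reconstructing p-values from published estimate/CI pairs is
limited by the printed precision of the inputs: interval endpoints carrying
only one or two significant digits can shift the implied p by several
units in its last digit.
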