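---
title: "Methods: blood-pressure EWAS and causal inference in discordant MZ twins"
author: "twinEWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood-pressure EWAS and causal inference in discordant MZ twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design

Monozygotic (MZ) co-twins share their genome and much of their early
environment. When co-twins are discordant for a trait, per-pair contrasts of
trait and DNA methylation remove genetic and shared-environment confounding
that plagues unrelated-sample EWAS. `twinEWAS` implements the full analysis
stack for such a study of blood pressure measured on RRBS methylomes:

1. phenotype derivation and discordant-pair selection,
2. CpG matrix QC and the beta-to-M transform,
3. reference-free cell-type components (ReFACTor style),
4. per-CpG association by pair-clustered Gaussian GEE with sandwich inference
   and tiered significance,
5. comb-p style DMR calling (distance-binned autocorrelation,
   Stouffer–Liptak window adjustment, peak finding,
   Stouffer–Liptak–Kechris regional p),
6. bidirectional ICE FALCON causal inference with a pair-level bootstrap,
7. nearest-gene annotation, case–control validation statistics and the
   intra-pair partial correlations used in power arguments.

Because the underlying cohort data are not publicly deposited, the package
ships a seeded synthetic generator that reproduces the statistical structure
the analysis assumes; every stage is exercised against it.

# Models and assumptions

## Phenotype derivation

The working blood pressure of an individual is the arithmetic mean of three
repeated readings. Derived values beyond three cohort standard deviations
from the cohort mean are set missing. We apply the rule to the derived mean
(not to single readings): the measurement description places the outlier rule
after averaging. Pairs missing a derived value in either member are excluded
from that trait's analysis; a pairwise design needs both members. Discordance
selection keeps pairs with |difference| at or above 2 mmHg (SBP) or
1 mmHg (DBP), boundary inclusive.

## QC and the M-value

CpGs are dropped when their mean beta is below 0.01 or when more than 10
observations are missing (10 missing is kept — the rule is strict). Coverage,
when present, is capped at each sample's 90th percentile; whether the
published pipeline capped per sample or globally is not stated, and we chose
per sample (the convention of the smoothing tools RRBS data pass through
upstream); the quantile is configurable. The analysis scale is the logit2
M-value `M = log2(beta/(1-beta))` (Du 2010). A bare `log2(beta)` would map
fully methylated sites to 0 and is not an M-value; beta is clipped to
[0.001, 0.999] first so M stays finite, with configurable bounds.

## Cell-type components

Whole blood is a mixture; composition differences confound bulk methylation.
With no reference panel in scope the package re-implements the ReFACTor
procedure: standardize sites, rank-`k` truncated SVD, score each site by the
distance between its standardized row and its rank-`k` reconstruction, keep
the `t` best-reconstructed sites, and take the first `d` principal-component
score columns of that sub-matrix. Defaults `k = d = 5`, `t = 500`
(studies of this design typically fix only the number of components used
downstream; `t` follows the ReFACTor default scaled to desk-size data). Ties on the reconstruction distance break
toward the lower genomic coordinate so output is deterministic; missing
entries are mean-imputed per site inside this operation only. Components are
computed once on the union of analysed individuals.

## Pair-clustered GEE

Association is the marginal linear model `M ~ BP + age + sex + components`
fitted by generalized estimating equations with an exchangeable working
correlation inside twin pairs and cluster-robust (sandwich) standard errors;
p-values are two-sided Wald with a normal reference (with 50–100 clusters the
t correction is negligible). Two substantive choices:

* **Orientation.** Published descriptions of this design often leave the
  regression outcome ambiguous. We
  regress M on BP — the adjustment set (cell composition) confounds
  methylation, and the reported coefficients (~0.01 M per mmHg) read
  naturally in that orientation. `orientation = "bp_outcome"` reverses it.
* **Finite-sample correction.** The plain sandwich estimator is biased low
  with O(100) clusters; the package multiplies it by `K/(K - p)` (clusters
  over clusters minus parameters). Without it, null simulations show an
  inflation factor of ~1.12; with it ~1.0 and null p-values pass a
  Kolmogorov–Smirnov uniformity test.

With the working correlation set to independence the point estimate equals
OLS exactly, which the tests use as an oracle. CpGs with fewer than 10
complete pairs, or singular designs, yield flagged rows rather than errors.

Significance tiers, first match wins: *genomewide* (BH FDR q < 0.05),
*suggestive* (p < 1e-6), *weaker-than-suggestive* (p < 1e-5), *top*
(p < 1e-4), else *ns*. "Top CpGs" passed to causal inference are all rows
with p < 1e-4 regardless of label.

## DMR calling

The comb-p recipe over EWAS p-values: probit transform
`z = qnorm(1 - p)`; Pearson autocorrelation of z in distance bins (50 bp bins
to 500 bp); per-probe Stouffer–Liptak combination over a ±200 bp window with
the binned correlations as `Sigma` (diagonal 1, negatives floored at 0,
beyond-range treated as 0); candidate regions are maximal runs of probes with
adjusted p below 0.01 separated by at most 200 bp, singletons discarded. No comb-p
parameters are mandated by the design; these are the tool's conventional
defaults and all are configurable.

Scoring combines the *original* member p-values under `Sigma`
(`slk_p`). Because candidates are selected exactly where adjusted p-values
are small, `slk_p` is biased small; calling therefore uses the Šidák
companion `1 - (1 - slk_p)^(covered/n_probes)`, the correction for the number
of same-sized probe sets tiling the probe-covered genome. On a uniform-null
5,000-probe genome the raw `slk_p < 0.05` rule calls ~10 regions per genome
while the Šidák rule calls essentially none, and an implanted 10-probe region
is still recovered in over 90% of seeds — both facts are asserted in the test
suite. `slk_p` stays in every output for comparability with published tables.
One numerical note: since `Sigma` has non-negative entries and unit diagonal,
the Stouffer–Liptak denominator `1'Sigma 1 >= n` is always positive, so no
positive-semidefinite repair can be needed for the quantity used; a guard
falls back to the identity matrix should the form ever be non-positive.

## ICE FALCON

For exposure x and outcome y on pair-long data (each twin once as self):

* M1: `y_self ~ x_self` — beta_self (association including any causal and
  familial part),
* M2: `y_self ~ x_cotwin` — beta_cotwin (familial part only),
* M3: `y_self ~ x_self + x_cotwin` — beta'_self, beta'_cotwin.

All three are pair-clustered GEE with age and sex (plus cell components when
methylation is the outcome; this covariate set is a design choice of the
package). Causation in the modeled direction
attenuates the co-twin coefficient far more than the self coefficient:
verdicts are *causal* when the co-twin change is significant and
|cotwin change| / |self change| exceeds 1.5, *familial confounding* when the
co-twin change is significant with a ratio at or below 1.5, otherwise
*inconclusive* with the ratio unreported — mirroring the dash pattern of the
published table, in which every unreported ratio coincides with a
non-significant co-twin change.

The change p-values come from a pair-level nonparametric bootstrap (resample
pairs with replacement, recompute the three models, B = 1000, seeded, normal
approximation on the bootstrap SE): the reference approach for ICE FALCON
change inference; reference analyses rarely state their change-inference
method, so only the coefficient/ratio arithmetic is held to reproduce
published values, and it does.

## Validation and power statistics

Candidate CpGs are compared between hypertension cases and controls by a
two-sided Wilcoxon rank-sum test (exact when the smaller group has at most 8
tie-free observations, normal approximation with continuity correction
otherwise) and by logistic regression of case status on methylation adjusted
for BMI, TG and FBG, with constant covariates dropped and perfect separation
flagged. The power argument's quantity — the partial correlation between
intra-pair BP difference and intra-pair M difference, adjusted for age and
sex — is computed by residualizing both difference vectors on the pair-level
covariates and correlating the residuals; the sign convention is twin 1 minus
twin 2, and only the magnitude enters power reasoning.

# The synthetic generator

Each pair draws a standard normal familial factor F (one latent standing in
for genetic plus shared-environment background — sufficient for ICE FALCON's
purposes). Signal-CpG M-value latents have sd `familial_load_m` (default 1)
and within-pair correlation `intra_pair_rho` (default 0.6, mirroring a
blood-pressure heritability near 0.6); null CpGs get the same moments from
pair-private factors that never touch BP. SBP is
`128 + 0.4 (age - 52) + 5 male + causal term + familial_load_bp * F + noise`
with `familial_load_bp = 8` and noise sd 16 mmHg: the cohort being emulated
reports an SBP spread of roughly sd 20 mmHg and a median intra-pair |dSBP| of
18 mmHg among selected discordant pairs, and these values land there. DBP is
derived from SBP with its own noise. Scenarios:

* `meth_causal`: SBP gains `causal_effect` (default 15 mmHg per M-unit)
  times the mean signal latent;
* `bp_causal`: the arrow reverses — each signal CpG gains
  `causal_effect` (default 0.02 M per mmHg, i.e. ~12% of M variance,
  the scale implied by the published intra-pair partial correlations) times
  centred SBP. In this scenario the signal latents use CpG-private pair
  factors, so the only methylation–BP link is the causal one and direction
  recovery is actually identifiable;
* `confounded`: no arrow, both familial loadings active;
* `null`: no signal at all.

Observed beta-values mix five Beta-distributed cell-type basis methylomes
with Dirichlet(12, 6, 4, 2, 1) individual fractions (a granulocyte-dominated
blood-like simplex), add the latent on the M scale, then truncated Gaussian
technical noise (sd 0.02) and clipping to (0.001, 0.999). Null CpGs draw
bimodal Beta(0.4, 0.4) basis profiles; signal CpGs draw centred Beta(5, 5)
ones, because trait-associated CpGs are intermediate-methylation variable
sites and a latent shift implanted at beta near 0 or 1 would vanish in the
bounded beta scale. A `missing_rate` knob exists but makes no claim of
matching any real missingness pattern. `implantDmr()` inserts a run of
spatially correlated BP-associated probes as ground truth for the DMR caller.

What the generator does **not** emulate: read-level sequencing noise,
coverage-dependent precision, genomic context (islands/shores), age or sex
effects on methylation, and realistic linkage of the biochemical covariates.
Passing tests demonstrate the pipeline's statistical behaviour under its own
assumptions, not performance on real RRBS data.

## A sharp edge worth knowing

With 10% of a desk-scale genome loading on a single shared factor, the
reference-free components *correctly* absorb that factor as if it were a
cell type, removing the signal. This is a genuine property of reference-free
correction, not a bug; it is why the FDR study uses the `bp_causal` scenario
(per-CpG independent associations) with age and sex adjustment, where the cell
mixture is by construction independent of BP. The component-adjustment test
instead sets `cell_bp_effect > 0` so composition genuinely confounds BP, and
asserts that including components deflates null inflation.

# Problem sizes and numerical choices

Simulation-backed checks run at sizes chosen to keep the full suite
comfortable on a laptop-class single core: 2,000 CpGs x 100 pairs for
calibration and FDR studies (50 replicates), 300-CpG genomes for DMR
recovery (50 replicates), 1,000 bootstrap replicates for ICE FALCON
acceptance runs and 200–400 for smoke-level tests. p-values are clamped to
[1e-15, 1 - 1e-15] before probit transforms; combined region p-values are
floored at 1e-300; the exchangeable correlation estimate is clamped to
±0.95; GEE iterations stop at a 1e-8 coefficient change. The published
table's ratio arithmetic is verified within the error bound propagated from
its 3-decimal printed inputs.

# Known limitations

* Clusters larger than two are rejected: this is a twin-pair engine, not a
  general GEE replacement.
* Wald inference uses a normal reference; with very few pairs (< 30) a t
  reference would be less liberal.
* ICE FALCON direction-finding degrades when the exposure side contains the
  outcome almost verbatim (strong reverse causation): with half of M variance
  driven by BP, both orientations look causal. The generator's defaults keep
  the causal share realistic so the limitation stays visible without
  dominating.
* `nearestGene()` imposes no search radius; distance is reported so users can
  filter.

# Worked example

```{r, eval = FALSE}
library(twinEWAS)
se <- simulateTwinCohort(simScenario("meth_causal", n_pairs = 60,
                                     n_cpgs = 2000, n_signal_cpgs = 10,
                                     seed = 7))
se <- deriveBP(se, "SBP")
se <- selectDiscordantPairs(se, "SBP")
se <- betaToM(qcFilterCpgs(capCoverage(se)))
comp <- refactorComponents(se)
rows <- runEwas(se, "SBP", comp)
dmrs <- callDmrs(rows)
ice <- runIceFalcon(se, "SBP", topCpgs(rows), components = comp, seed = 7)
```
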