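---
title: "Quantitative-genetic analysis of germination under elevated temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-genetic analysis of germination under elevated temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtherm)
```

## The problem and the model

Seed lots ("accessions") from structured diversity panels — wild
populations and cultivated landraces — differ both in their germination
behaviour and in their genome-wide relatedness, and the two are
confounded: wild and landrace accessions form distinct genetic clusters.
`germtherm` implements the analysis chain that separates these signals
for two germination traits measured under a cold (20°C) and a warm
(30–35°C) treatment:

* **germination time (GT)**: hours from imbibition to radicle emergence,
  right-censored at 168 h (a seed that has not germinated by then is
  declared non-germinated and its time is undefined);
* **germination rate (GR)**: the per-seed 0/1 indicator of germination
  within 168 h.

The central model is the animal-model gBLUP: for a seed of accession $i$,

$$y_{ijkl} = \mu + \mathrm{temperature} + \mathrm{type}_i +
\mathrm{batch}_j + \mathrm{year}_k + \mathrm{conservation}_l + g_i +
e_{ijkl},$$

with $g \sim N(0, \sigma_G^2 G)$ and $e \sim N(0, \sigma_e^2 I)$, where
$G$ is the genomic relationship matrix estimated from SNP dosages.
Heritability is $h^2 = \sigma_G^2 / (\sigma_G^2 + \sigma_e^2)$. The suite
runner refits the model on subdivided data — per type (the "b" fits) and
per type × temperature (the "c" fits) — because wild and landrace
accessions differ strongly in variance; per-temperature gBLUPs from the
"c" fits are the basis of all downstream analyses.

GR is binary, so it is handled in two stages rather than by a joint
binary GLMM (whose convergence is not reliably attainable): a stage-one
binomial-logit GLM removes the nuisance design (batch, year, and the
conservation × temperature interaction), and its residuals *on the latent
scale* ("GRA") are then fitted with the Gaussian gBLUP engine. This is
the GRAMMAR-family pretreatment. The latent residual is not uniquely
defined by that convention; we default to the **working residual**
$(y-\hat\mu)/(\hat\mu(1-\hat\mu))$, which is the linear-predictor-scale
residual of IRLS, and expose deviance and Pearson residuals as
alternatives (the choice is recorded in the output metadata). The
stage-one model keeps the conservation and temperature main effects
alongside the printed interaction: dropping the mains would make the
interaction estimate depend on the dummy coding.

Downstream, per accession: $C$ and $W$ are the cold and warm gBLUPs, heat
tolerance is $H = W - C$, and three OLS regressions quantify

1. ranking conservation across temperatures: $W = \mu_4 + b\,C + e$
   (slope near 1 with high adjusted $R^2$ means minimal G×E);
2. local adaptation: $H = \mu_5 + b_C\,C + b_l\,\mathrm{latitude} + e$,
   fitted per type and jointly, with $C$ controlling for the baseline —
   a Finlay–Wilkinson-style regression on an environmental index
   (latitude is used directly as the climate proxy; it correlates
   strongly with annual mean temperature);
3. field validation: $E = \mu_6 + \mu_3 + b\,C + e$, where $E$ is the
   field emergence rate and $\mu_3$, the cold-model intercept, enters as
   a **fixed offset** — it is a known quantity from another fit, so it is
   subtracted from $E$ rather than re-estimated.

Significance of single coefficients uses a Z-test (the large-sample
approximation to the t-test); factor-level comparisons use Tukey's HSD
with $q = |\Delta|/(SE(\Delta)/\sqrt2)$ against the studentized-range
distribution with the residual degrees of freedom.

## The EM-REML engine

Variance components are estimated by EM-REML on the mixed-model
equations, with one average-information (AI) step at convergence to
obtain their standard errors — EM for its guaranteed monotone likelihood
ascent (asserted on every fit), AI only for curvature. Implementation
choices that matter:

* **Convergence.** We iterate until the restricted log-likelihood changes
  by less than 1e-10 *and* the relative change of both components is
  below 1e-8, with a cap of 2000 iterations. EM converges only linearly
  near the optimum; a looser likelihood-only rule (e.g. 1e-6) leaves the
  components several decimals short of the closed-form solution on
  balanced designs, which is why both criteria are used.
* **Bounds.** Components are bounded below at 1e-8; a fit pinned there is
  flagged `boundary`, and a non-converged fit is returned with its trace
  rather than raised as an error.
* **Bending.** Whenever a relationship matrix must be factorised (here
  and in the simulator), a diagonal ridge of 1e-6 is added while the
  smallest eigenvalue is below 1e-8. Small panels and LD-pruned SNP sets
  are routinely rank-deficient; the same rule is applied everywhere.
* **Aliasing.** Fixed-effect columns made constant by subsetting (e.g.
  temperature inside a per-temperature fit) are dropped by pivoted rank
  detection with a logged message.
* Accessions present in $G$ but without phenotype rows receive gBLUPs
  through the relationship matrix (empty incidence columns are valid in
  the MME).
* Conservation days enter standardized; temperature is a two-level
  factor, and per-°C effects are obtained post hoc by dividing the
  contrast by the species' temperature difference.

## Variant filtering

The filter chain reproduces a resequencing-panel cleaning recipe as
explicit, counted, order-preserving steps: accession mean depth strictly
above 20; biallelic SNPs only (indels and multiallelic sites removed);
SNPs strictly closer than 5 bp to an indel anchor removed (indel
positions are recorded *before* the indel records themselves are
excluded); site mean depth inside the closed 5th–95th percentile band;
mapping quality strictly above 40; chromosome scaffolds only; removal of
any site where some accession has both allele depths below 10 (this also
removes every site with a missing call, since a missing call carries zero
depths); and finally greedy LD pruning (keep a site unless its squared
dosage correlation with a previously kept site in the trailing window
exceeds 0.2; correlation against a monomorphic site is defined as 0).

Conventions that had to be fixed because the recipe leaves them open, all
exposed in `filter_config()`:

* the depth percentile uses linear interpolation between order statistics
  (`stats::quantile` type 7);
* the percentile band is computed on the *current* (partially filtered)
  site set, so this step — unlike the others — is not idempotent in
  general: re-applying it to its own output computes new percentiles;
* the prune window of "1000" is read literally as 1000 **sites**, with a
  bp dialect available;
* indel proximity is measured to the indel's anchor position, not its
  span end.

## The synthetic cohort

The generator supplies inputs with exactly the statistical structure the
models assume, so every stage is verifiable offline. Genotypes follow the
Balding–Nichols model: ancestral frequencies Uniform(0.05, 0.95),
population frequencies Beta-diverged with parameter $F_{ST}$, Dirichlet
admixture, dosages Binomial(2, freq); monomorphic columns are re-drawn.
Admixture weights are rotated so the largest weight falls on a
round-robin "primary" population — this yields balanced, labelled
clusters (needed for structure-recovery checks) while keeping admixture
continuous. Accessions of population 1 are labelled landraces, the rest
wild, mirroring the wild–landrace clustering of real panels.

Phenotypes: cold genetic values $a_C \sim N(0, \sigma_g^2 G)$; warm
values $a_W = \rho a_C + \sqrt{1-\rho^2}\,a_\perp + s\,z(\mathrm{lat})$,
so the cross-temperature genetic correlation $\rho$ and a latitude effect
$s$ on heat tolerance are both explicit. The latitude slope is applied on
the *standardized* latitude scale, and the truth record also stores the
implied per-degree slope, so recovery can be checked on either scale.
Per-seed GT adds the design fixed effects and a Gaussian residual
(truncated below at 0.5 h; a log-normal residual option exists — the
hour-valued, censored nature of real germination times does not identify
the distributional form, and no claim is made about which matches real
data). The binary outcome follows an independent logistic liability with
its own genetic values (default liability-scale additive variance 1.4,
i.e. $h^2 \approx 0.3$ against the logistic residual variance
$\pi^2/3$); a seed is recorded germinated iff its liability draw succeeds
*and* its GT falls below the censoring threshold, and censored or
non-germinated seeds contribute zeros to GR while being excluded from GT
fitting. Emergence is a logistic function of the cold GR genetic value
plus noise.

Default effect sizes are chosen to resemble a *Brassica*-like panel:
GT intercept 60 h, warm effect −16 h, wild-type penalty +26 h, batch SD
3 h, conservation slope 0.01 h/day, $\sigma_g^2 = 180$,
$\sigma_e^2 = 640$ (so $h^2 \approx 0.22$, in the range reported for
germination traits), $\rho = 0.9$ and a small negative latitude slope.
The contaminated-VCF writer plants requested counts of filter violations
at recorded positions; clean cells are written at constant depth 50 so
the depth-percentile band is degenerate and removes exactly the planted
outliers, and planted positions are spaced ≥ 20 bp so an indel/SNP pair
never grazes a neighbouring record.

What the generator does **not** emulate: pooled sequencing (accessions
are diploid dosage calls, matching the deposited data model, not pool
frequencies), linkage disequilibrium along the chromosome (SNPs are drawn
independently, so LD pruning on clean simulated data removes only chance
correlations), dormancy, maternal effects, and spatial field structure in
emergence. Passing tests therefore validate the estimation machinery
under the assumed model, not the biology of any real panel.

## Problem sizes and numerical checks

The test suite and acceptance script run at deliberately modest sizes,
chosen as the smallest scales at which the statistical claims are stable:
the filter fixture uses ~2,000 sites × 30 accessions; heritability
recovery uses 50 cohorts of 100 accessions × 50 seeds at $h^2 = 0.3$
(the mean estimate must fall within ±0.03 of truth); the G×E checks use
11 null cohorts ($\rho = 1$, no latitude effect: median cross-temperature
slope within ±0.1 of 1, latitude coefficient non-significant in ≥ 90%)
and 5 low-noise cohorts with a planted slope (median relative error
< 10%). Oracles are independent of the code paths they check: closed-form
ANOVA-REML on balanced designs, a dense-matrix REML likelihood maximised
numerically, brute-force GRM double loops, `stats::cmdscale`, closed-form
logits, and normal-equation OLS.

## Known limitations

* The EM-REML engine fits one random genetic effect; multi-trait and
  multi-kernel models are out of scope.
* GT is analysed as Gaussian despite censoring; the two-stage GR analysis
  transfers binary information through a residual approximation rather
  than a joint likelihood. Both choices privilege convergence
  reliability over model fidelity, and both are inherited by design.
* Emergence is analysed on the raw proportion scale (configurable), so
  predictions are not constrained to [0, 1].
* With two temperatures per species, temperature-as-factor and
  temperature-as-slope parameterisations are equivalent; per-°C effects
  are derived, not fitted.
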