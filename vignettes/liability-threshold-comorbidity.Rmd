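---
title: "Models and methods: liability-threshold comorbidity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: liability-threshold comorbidity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabkin)
```

## The scientific problem

Two clinically diagnosed disorders co-occur within individuals and
cluster within families. Three designs triangulate whether that overlap
is genetic: (i) *familial coaggregation* — does the risk of disorder Y in
relatives of probands with disorder X decline with relatedness? (ii)
*quantitative genetic modeling* — comparing full sisters with maternal
half-sisters, who are assumed to share family environment equally but
differ in additive-genetic sharing (coefficients .50 vs .25), partition
the liability (co)variance into additive genetic (A), dominance (D),
shared environment (C) and unique environment (E, including measurement
error); (iii) *polygenic scores* — do common-variant risk scores from an
independent discovery GWAS predict the corresponding symptom dimension in
a population cohort? liabkin implements all three arms plus the synthetic
cohorts needed to validate them.

## Liability-threshold model

A binary diagnosis is modeled as `D = 1{L > t}` with `L ~ N(0, 1)` and
`t = qnorm(1 - K)` for prevalence `K` ([threshold_from_prevalence()]).
For a pair of relatives measured on two traits, the latent vector
`(L_x1, L_y1, L_x2, L_y2)` is multivariate normal with correlation matrix
assembled by [pair_model_matrix()]:

* within-individual cross-trait: `covA + covD + covC + covE`;
* cross-member same-trait: `kA*a2 + kD*d2 + kC*c2`;
* cross-member cross-trait: `kA*covA + kD*covD + kC*covC`,

where `(kA, kD, kC)` are the sharing coefficients of the relative class.
Component covariances are parameterized as `covA = rA * sqrt(a2_x a2_y)`
etc.; since each implied matrix is a sum of Kronecker products of PSD
blocks, every parameter point yields a valid covariance — the same
guarantee a Cholesky parameterization gives, with directly interpretable
parameters.

The observed data are pair contingency tables: 3 categories
(both affected / both unaffected / discordant) for one trait, 16 cells
for two traits. The log-likelihood is the multinomial kernel
`sum n_cell * log p_cell`, with cell probabilities equal to rectangle
probabilities of the thresholded normal. Unordered pairs are handled by
symmetrizing counts over member order (equivalent to double entry at half
weight); because thresholds are shared between the two members of a pair,
the model itself is exchangeable and symmetrization leaves the likelihood
unchanged while keeping counts interpretable. Fractional counts are
accepted so that tables reconstructed from published summaries (where
only the total number of discordant pairs is printed and is split evenly
across the two off-diagonal cells) are first-class inputs.

### Numerical integration

Rectangle probabilities are computed deterministically, not by Monte
Carlo. The bivariate CDF uses the Drezner–Wesolowsky angle-form
Gauss–Legendre quadrature for |rho| ≤ .925 and a smallest-orientation
conditional reduction near |rho| = 1, vectorized over inputs (validated
to ~5e-10 against an external implementation). Three- and
four-dimensional rectangles condition on the first one or two variables —
transformed to [0, 1] by the truncated-normal inverse CDF and integrated
with Gauss–Legendre — leaving an exact conditional bivariate CDF inside.
The dedicated 16-cell routine shares outer nodes across all cells, so one
likelihood evaluation costs four vectorized bivariate-CDF calls per
relative class. Node counts: 96 for the user-facing
[orthant_probability()] (absolute error ≤ 1e-6 on random 4-dim
matrices), 16 for the fit kernel (cell error ~2.5e-6, negligible against
sampling noise at register-scale counts, and ~100x cheaper — the
100-replicate recovery study depends on this). Probabilities are floored
at 1e-300 before logging; degenerate within-member blocks (|r| → 1)
return a large penalty to the optimizer rather than an error.

### Estimation

[tetrachoric_mle()] fixes thresholds at the margins' normal quantiles and
profiles the 2×2 multinomial likelihood over rho with a golden-section
search; the SE comes from the observed information, and |rho| > .997 is
flagged as a boundary estimate. A brute-force grid search over rho is the
test oracle.

[fit_univariate()] and [fit_bivariate()] maximize the joint likelihood
over relative classes with BFGS on transformed parameters (logit for
variance fractions, softmax for three-component models, atanh for
component correlations), numeric gradients, and a method-of-moments start
assembled from per-class tetrachorics. The warm start makes random
restarts unnecessary in practice; seeded jittered restarts are triggered
only on non-convergence. Standard errors and 95% CIs for derived
quantities (a², coheritability, rg) use the delta method on the inverse
observed information (numDeriv Hessian at the optimum). AIC is
`-2 loglik + 2k` with `k` the number of free optimizer parameters;
[select_model()] takes the minimum, breaking exact ties toward fewer
parameters. ACDE is deliberately absent: with only two sister classes it
is not identified.

**Thresholds are estimated per relative class** (shared between the two
members of a pair, free across classes). This is a deliberate choice: in
register data the observed margins of full-sister and maternal
half-sister samples differ substantially (half-sibships are selected for
maternal characteristics correlated with diagnosis rates), and forcing a
common threshold makes the model absorb the margin misfit into the
correlation parameters — in the bundled reproduction it pushes the ADHD
additive fraction from .836 to .90, outside the published interval. A
`thresholds = "shared"` option remains for strictly stationary designs.

[solve_ae_from_correlations()] is the closed-form companion: a
pair-count-weighted least-squares solution of the linear AE system
(`r_class = kA * a2`, `cross_class = kA * covA`, `phen = covA + covE`)
applied to published correlation sets, used where the full 16-cell tables
are not public. Negative implied components are clipped to the boundary
and flagged, never silently.

## Coaggregation arm

[coaggregation_or()] double-enters each pair (both members serve once as
index, once as relative), regresses the relative's diagnosis on the
index's diagnosis with both members' birth years (centered, continuous)
and sexes as covariates, and clusters the sandwich variance on family id
— double entry is why cluster-robust variance is mandatory. Point
estimation is `stats::glm` maximum likelihood; `sandwich::vcovCL` stacks
scores by cluster and reduces to the heteroskedasticity-robust estimator
for singleton clusters. Separation is flagged when any fitted probability
is within 1e-8 of 0/1 or the exposure log-odds diverges; flagged
estimates are reported, not suppressed. Including *both* members'
covariates is the conservative reading of "adjusted for birth year and
sex" in pair data. Birth year is continuous by default; a categorical
banding can be passed through the covariates argument.

## PRS arm

QC bounds are inclusive (MAF ≥ .05 computed as `min(f, 1-f)`; INFO ≥
.80); strand-ambiguous variants (A/T, C/G) are dropped by default because
their orientation cannot be reconciled across studies without frequency
heuristics. Clumping is the standard greedy rule — smallest p first,
removing correlated neighbours (dosage Pearson r² in a caller-supplied
reference panel, > .1 within ±1000 kb) — with a deterministic p-then-id
tie-break; an oracle that checks the retained/removed sets against the
rule itself validates it on random panels. Scoring uses strict `p <
threshold`, dosage flips (`2 - dosage`) for swapped allele labels, and
mean imputation (`2 x` effect-allele frequency) for missing dosages.
ΔR² is the plain OLS R² difference between the full and the nested model
on the estimation sample, no small-sample adjustment. The association
model is an independence-working-correlation GEE: point estimates are
exactly OLS and inference is cluster-robust on twin-pair id, which is the
estimator the design requires, implemented as `lm` + `vcovCL`.

## What the synthetic cohorts emulate — and what they do not

[simulate_pedigree()] generates independent families in five structures
(full sibships, maternal/paternal half-sibships, three-generation cousin
families, twin sibships); relative classes are recoverable from parent
links alone, which the enumeration oracle tests exploit.
[simulate_liabilities()] draws family blocks from the exact multivariate
normal implied by the architecture — so cross-relative covariances match
the coefficient algebra by construction, not asymptotically. Defaults
mirror the register setting the package targets: birth years uniform on
1970–2005 (1992–2005 for the twin-cohort arm), sexes Bernoulli(.5),
default seed 20191015, and every stochastic operation takes an explicit
seed (results are byte-identical under a fixed seed).

Genotypes: per-block MAF uniform on the spec range, haplotypes as binary
Markov chains with the nominal adjacent allelic correlation hit exactly
(a thresholded Gaussian copula was considered and rejected: binarization
attenuates the realized r² below its nominal value, which would make
"block correlation .9 → adjacent r² ≈ .81" false by construction), and
Hardy–Weinberg dosages as sums of two haplotypes. The discovery sample is
drawn independently of the target cohort; summary statistics are marginal
per-variant OLS with simulated INFO (Beta(30, 2), so a realistic minority
falls below the .80 filter).

Symptom items load on a single latent factor correlated with the supplied
genetic value. Because categorization (3-level parent-report items,
6-level self-report items) attenuates Pearson correlations nonlinearly,
the generator inverts the exact categorized-correlation curve (computed
from bivariate-normal cell probabilities) so the emitted items achieve a
requested Cronbach alpha. Default response mixes give item means matching
typical population screening data (ADHD full-scale mean ≈ 1.8 of 19;
eating-disorder item mean ≈ 2.1 of 6).

Not emulated: recombination maps, assortative mating, X-linkage,
selection/participation bias, diagnostic misclassification, and secular
trends in diagnosis rates. Passing tests therefore demonstrate that the
estimators recover the parameters of this idealized generating process at
the stated sample sizes — not that register data meet those assumptions.
The environmental sharing of cousins and paternal half-siblings is not
identified by the sister design, so the simulator exposes their C
coefficient as an argument (default 0) rather than asserting a value.

## Problem sizes used by the validation suite

The suite sizes its simulations to be informative rather than exhaustive:
parameter recovery runs 100 replicates at 100,000 full-sister plus 20,000
half-sister pairs (register scale); null calibration of the coaggregation
CI runs 500 replicates of 1,500-family cohorts at 10% prevalence (higher
than registry prevalence, chosen so each scaled replicate has enough
events for a stable OR); clumping is checked against its oracle on 1,000
random 10-variant panels; and the end-to-end PRS recovery uses 30
replicates of an 800-variant panel with 6,000 discovery and 9,000 target
individuals at β ≈ .03 per SD — the magnitude reported for symptom-scale
PRS associations, where sign recovery (not precise estimation) is the
meaningful criterion, and the cohort size is chosen so the design power
for a positive sign exceeds 99% (standard error ≈ .008 against an
attenuated realized effect of ~.025).

## Known limitations

* Tetrachoric thresholds are fixed at margins rather than profiled
  jointly with rho; at register-scale counts the difference is far below
  the reported precision.
* Delta-method CIs for strongly nonlinear derived quantities
  (coheritability near 0 or 1) can cross the parameter boundary;
  likelihood-profile intervals are not implemented.
* The published-summary reconstruction assumes the discordant pairs split
  evenly across orientations; the published estimates were reproduced
  under that assumption and agree, but it remains an assumption.
* Covariate moderation of thresholds (birth-year or sex effects on
  prevalence within the pair sample) is not modeled.
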