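# liabkin

Genetically informative analyses of the overlap between two binary
disorders — familial coaggregation, liability-threshold quantitative
genetics in sister pairs, and polygenic risk scores — with a synthetic
cohort generator so every stage runs and is testable without access to
register or biobank data.

The package targets analysts working with clinically ascertained binary
diagnoses in relatives (e.g. ADHD and eating disorders in national
registers) and with genotyped symptom-scale cohorts. It implements three
complementary designs:

1. **Familial coaggregation.** For pairs of relatives of decreasing
   relatedness (full siblings, maternal/paternal half-siblings, cousins),
   the odds ratio of disorder *Y* in relatives of probands with disorder
   *X*, from double-entered pair data with logistic regression, covariate
   adjustment (birth year, sex of both members), and cluster-robust
   (sandwich) standard errors on family id. A gradient of ORs declining
   with relatedness indicates shared familial liability.

2. **Liability-threshold quantitative genetics.** Each disorder is a
   thresholded standard-normal liability: prevalence *K* fixes the
   threshold *t* = Φ⁻¹(1−K). Cross-relative tetrachoric correlations are
   estimated by maximum likelihood from pair 2×2 tables, and bivariate
   ACE/ADE/AE models decompose liability (co)variance using the sharing
   coefficients of full sisters (A: .50, D: .25, C: 1.00) and maternal
   half-sisters (A: .25, C: 1.00). The model for a pair is a 4-dimensional
   thresholded normal whose 16 cell probabilities enter a multinomial
   likelihood, fitted jointly across relative classes; AIC selects among
   ACE/ADE/AE. Reported quantities: heritability a², coheritability
   (covA / phenotypic liability covariance), genetic correlation
   rg = covA/√(a²ₓ·a²ᵧ), with delta-method CIs.

3. **Polygenic risk scores.** GWAS summary statistics are QC-filtered
   (MAF ≥ .05, INFO ≥ .80), LD-clumped (greedy, r² > .1 within 1000 kb),
   and scored at p-value thresholds {1e-5, .001, .01, .05, .10, .50, 1};
   standardized scores are regressed on symptom scales (sum-scored ADHD
   inventory, mean-scored eating-disorder inventory) under an
   independence-working-correlation GEE with twin-pair clustering,
   reporting β per SD of score and ΔR².

The synthetic-data module generates pedigrees with recoverable relative
classes, family-block multivariate-normal liabilities with known
architecture, LD-blocked diallelic genotypes with a disjoint discovery
GWAS, and discretized symptom items with a calibrated Cronbach alpha —
the ground truth against which every analysis stage is validated.

## Worked example

Simulate register-scale sister-pair tables under a known architecture and
recover it with the bivariate AE liability model:

```r
library(liabkin)

arch <- architecture_spec(a2 = c(.82, .45), rA = .37, rE = .15,
                          prevalence = c(.022, .01),
                          traits = c("adhd", "ed"))
tabs <- simulate_pair_tables(c(full_sister = 100000,
                               maternal_half_sister = 20000),
                             arch, seed = 42)
fit <- fit_bivariate(tabs, model = "AE", seed = 42)
fit
#> bivariate AE liability fit (full_sister + maternal_half_sister)
#>   a2_x = 0.815 (95% CI 0.756, 0.873)
#>   a2_y = 0.505 (95% CI 0.392, 0.618)
#>   coher_A = 0.912 (95% CI 0.647, 1.177)
#>   rg = 0.395 (95% CI 0.276, 0.513)
#>   loglik -38159.49, AIC 76334.98, k=8
```

The generating values (a² = .82/.45, rg = .37) fall inside every interval:
120,000 pairs at ~2% prevalence identify the additive fractions to a few
points and the genetic correlation to ~±.12.

The reproduction mode recomputes published register-study results from
bundled printed summary counts — nothing is copied; tetrachoric MLEs and
AE fits run on the reconstructed tables:

```r
rep <- reproduce_reference()
round(rep$adhd_a2, 3)                      # 0.836  (published ~82%, CI .78-.85)
round(rep$ae_solutions$an$coher_A, 3)      # 0.414  (published ~42%)
round(rep$ae_solutions$oed$rg, 3)          # 0.360  (published .37, CI .31-.42)
```

An end-to-end synthetic run of all three arms (prevalence table,
OR-by-relatedness table, biometric fits, per-threshold PRS associations):

```r
res <- run_all(run_config(seed = 1, output_dir = "reports"))
```

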