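# Domain types for the synthetic-cohort generator: the bivariate variance
# architecture on the liability scale, relative-class sharing coefficients,
# and the genotype-panel specification.

#' Bivariate liability architecture specification
#'
#' Describes the joint genetic/environmental architecture of two binary
#' traits on the liability scale: per-trait variance fractions for
#' additive-genetic (A), dominant-genetic (D), shared-environment (C) and
#' unique-environment (E) components, cross-trait component correlations,
#' and population prevalences that fix the diagnostic thresholds.
#'
#' @param a2,d2,c2,e2 length-2 numeric vectors of variance fractions per
#'   trait; each trait's fractions must sum to 1 (tolerance 1e-9) and be
#'   non-negative.
#' @param rA,rD,rC,rE cross-trait correlations of the respective
#'   components, in `[-1, 1]`.  A correlation for a component with zero
#'   variance in either trait is ignored (its covariance is 0).
#' @param prevalence length-2 vector of population prevalences in (0, 1).
#' @param traits character length-2 trait names.
#' @return an object of class `architecture_spec`.
#' @examples
#' arch <- architecture_spec(a2 = c(.82, .45), rA = .37,
#'                           prevalence = c(.022, .01),
#'                           traits = c("adhd", "ed"))
#' @export
architecture_spec <- function(a2 = c(0, 0), d2 = c(0, 0), c2 = c(0, 0),
                              e2 = NULL, rA = 0, rD = 0, rC = 0, rE = 0,
                              prevalence = c(.05, .05),
                              traits = c("trait_x", "trait_y")) {
  a2 <- rep_len(a2, 2); d2 <- rep_len(d2, 2); c2 <- rep_len(c2, 2)
  if (is.null(e2)) e2 <- 1 - a2 - d2 - c2 else e2 <- rep_len(e2, 2)
  fr <- rbind(a2, d2, c2, e2)
  if (any(fr < -1e-12)) stopf("variance fractions must be non-negative")
  fr[fr < 0] <- 0
  tot <- colSums(fr)
  if (any(abs(tot - 1) > 1e-9))
    stopf("per-trait variance fractions must sum to 1 (got %.12f, %.12f)",
          tot[1], tot[2])
  for (r in c(rA, rD, rC, rE))
    if (abs(r) > 1) stopf("cross-trait correlations must lie in [-1, 1]")
  if (any(prevalence <= 0 | prevalence >= 1))
    stopf("prevalences must lie strictly in (0, 1)")
  if (length(traits) != 2L || anyDuplicated(traits))
    stopf("need two distinct trait names")
  spec <- structure(list(
    a2 = unname(fr[1, ]), d2 = unname(fr[2, ]), c2 = unname(fr[3, ]),
    e2 = unname(fr[4, ]),
    rA = rA, rD = rD, rC = rC, rE = rE,
    covA = rA * sqrt(prod(fr[1, ])), covD = rD * sqrt(prod(fr[2, ])),
    covC = rC * sqrt(prod(fr[3, ])), covE = rE * sqrt(prod(fr[4, ])),
    prevalence = prevalence, traits = traits
  ), class = "architecture_spec")
  # implied 4x4 pair matrices must be PSD for every built-in relative class
  for (cl in c("full_sister", "maternal_half_sister",
               "paternal_half_sibling", "cousin")) {
    R <- pair_model_matrix(spec, relatedness_class(cl))
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stopf("implied pair liability matrix for class '%s' is not PSD", cl)
  }
  spec
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("Bivariate liability architecture\n")
  m <- rbind(a2 = x$a2, d2 = x$d2, c2 = x$c2, e2 = x$e2,
             prevalence = x$prevalence)
  colnames(m) <- x$traits
  print(round(m, 4))
  cat(sprintf("cross-trait correlations: rA=%.3f rD=%.3f rC=%.3f rE=%.3f\n",
              x$rA, x$rD, x$rC, x$rE))
  invisible(x)
}

#' Relative-class sharing coefficients
#'
#' Expected fractions of the A, D and C liability variance components
#' shared by a pair of the given class.  Full sisters share additive
#' variance with coefficient .50, dominance with .25 and the shared
#' environment fully; maternal half-sisters share additive variance with
#' coefficient .25 and the shared environment fully.  The environmental
#' sharing of paternal half-siblings and cousins is not identified by the
#' sister-pair design, so their C coefficient is exposed as an argument
#' (default 0).
#'
#' @param label one of `"full_sister"`, `"full_sibling"`,
#'   `"maternal_half_sister"`, `"maternal_half_sibling"`,
#'   `"paternal_half_sibling"`, `"cousin"`.
#' @param c_coefficient optional override of the shared-environment
#'   coefficient (used for paternal half-siblings and cousins).
#' @return an object of class `relatedness_class` with fields `label`,
#'   `kA`, `kD`, `kC`.
#' @export
relatedness_class <- function(label, c_coefficient = NULL) {
  label0 <- sub("_sister$", "_sibling", label)
  co <- switch(label0,
    full_sibling          = c(kA = .50,  kD = .25, kC = 1),
    maternal_half_sibling = c(kA = .25,  kD = 0,   kC = 1),
    paternal_half_sibling = c(kA = .25,  kD = 0,   kC = 0),
    cousin                = c(kA = .125, kD = 0,   kC = 0),
    stopf("unknown relative class '%s'", label))
  if (!is.null(c_coefficient)) {
    if (c_coefficient < 0 || c_coefficient > 1)
      stopf("C coefficient must lie in [0, 1]")
    co["kC"] <- c_coefficient
  }
  structure(list(label = label, kA = unname(co["kA"]),
                 kD = unname(co["kD"]), kC = unname(co["kC"])),
            class = "relatedness_class")
}

as_relatedness_class <- function(x) {
  if (inherits(x, "relatedness_class")) x else relatedness_class(x)
}

#' Genotype panel specification for the simulator
#'
#' Parameters of the simulated diallelic panel: panel size, linkage-
#' disequilibrium block structure, allele-frequency range, polygenic
#' architecture of the simulated discovery trait, and the sizes of the
#' (disjoint) discovery and target samples.
#'
#' @param n_variants number of variants.
#' @param block_length number of variants per LD block.
#' @param block_r correlation between adjacent alleles within a block, in
#'   `[0, 1)`.
#' @param maf_range length-2 minor-allele-frequency range within (0, 0.5].
#' @param n_causal number of causal variants (`<= n_variants`).
#' @param h2 variance of the trait explained by the causal variants
#'   jointly, in `[0, 1)`.
#' @param n_discovery,n_target sample sizes of the discovery GWAS and the
#'   target cohort.
#' @param bp_spacing base-pair distance between adjacent variants.
#' @return an object of class `geno_panel_spec`.
#' @export
geno_panel_spec <- function(n_variants = 1000, block_length = 10,
                            block_r = 0.6, maf_range = c(0.05, 0.5),
                            n_causal = 50, h2 = 0.3,
                            n_discovery = 5000, n_target = 2000,
                            bp_spacing = 10000) {
  if (!is_count(n_variants) || !is_count(block_length))
    stopf("n_variants and block_length must be positive integers")
  if (block_r < 0 || block_r >= 1) stopf("block_r must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must lie within (0, 0.5]")
  if (n_causal > n_variants) stopf("causal count exceeds panel size")
  if (h2 < 0 || h2 >= 1) stopf("h2 must lie in [0, 1)")
  structure(list(n_variants = as.integer(n_variants),
                 block_length = as.integer(block_length),
                 block_r = block_r, maf_range = maf_range,
                 n_causal = as.integer(n_causal), h2 = h2,
                 n_discovery = as.integer(n_discovery),
                 n_target = as.integer(n_target),
                 bp_spacing = as.integer(bp_spacing)),
            class = "geno_panel_spec")
}
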