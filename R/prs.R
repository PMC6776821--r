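# Polygenic risk scores: summary-statistic QC, greedy LD clumping,
# p-value-threshold scoring, symptom-scale scoring, internal consistency,
# and clustered linear association tests.

#' QC-filter GWAS summary statistics
#'
#' Retains variants with minor allele frequency `>= maf_min` (computed as
#' `min(freq, 1-freq)`) and imputation quality `INFO >= info_min`; both
#' bounds inclusive.  Strand-ambiguous variants (A/T, C/G) are dropped by
#' default since their orientation cannot be reconciled across studies.
#'
#' @param ss summary-statistics data.frame (see [read_sumstats()]).
#' @param maf_min minor-allele-frequency lower bound.
#' @param info_min INFO lower bound.
#' @param drop_ambiguous drop A/T and C/G variants.
#' @return filtered summary statistics.
#' @export
qc_filter <- function(ss, maf_min = 0.05, info_min = 0.80,
                      drop_ambiguous = TRUE) {
  need <- c("snp", "a1", "a2", "beta", "p", "freq")
  miss <- setdiff(need, names(ss))
  if (length(miss)) stopf("missing sumstats column(s): %s",
                          paste(miss, collapse = ", "))
  keep <- pmin(ss$freq, 1 - ss$freq) >= maf_min
  if (is.null(ss$info)) {
    warning("no INFO column; passing all variants through the INFO filter")
  } else {
    keep <- keep & ss$info >= info_min
  }
  if (drop_ambiguous) {
    amb <- (ss$a1 == "A" & ss$a2 == "T") | (ss$a1 == "T" & ss$a2 == "A") |
      (ss$a1 == "C" & ss$a2 == "G") | (ss$a1 == "G" & ss$a2 == "C")
    keep <- keep & !amb
  }
  ss[keep, , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclumped variant as an index and
#' removes every variant within `window_kb` of it (same chromosome) whose
#' squared dosage correlation with the index in the reference panel
#' exceeds `r2_max`; returns the surviving index variants.  Variants not
#' covered by the reference are dropped with a message.
#'
#' @param ss summary statistics (post-QC).
#' @param reference list with `geno` (n x m dosage matrix) and `map`
#'   (with `id`, `chr`, `pos`) — any reference panel, e.g. the simulated
#'   one.
#' @param r2_max squared-correlation threshold (clump if r2 > r2_max).
#' @param window_kb physical window half-width in kilobases.
#' @return clumped summary statistics (subset of rows of `ss`).
#' @export
ld_clump <- function(ss, reference, r2_max = 0.1, window_kb = 1000) {
  m <- match(ss$snp, reference$map$id)
  if (anyNA(m)) {
    message(sum(is.na(m)), " variant(s) absent from the reference; dropped")
    ss <- ss[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  if (!nrow(ss)) return(ss)
  G <- reference$geno[, m, drop = FALSE]
  ord <- order(ss$p, ss$snp)               # deterministic tie-break
  alive <- rep(TRUE, nrow(ss))
  keep <- logical(nrow(ss))
  win <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & ss$chr == ss$chr[i] &
                    abs(ss$pos - ss$pos[i]) <= win)
    if (length(cand)) {
      r <- suppressWarnings(cor(G[, i], G[, cand]))
      r[is.na(r)] <- 0
      alive[cand[r^2 > r2_max]] <- FALSE
    }
  }
  ss[keep, , drop = FALSE]
}

#' Polygenic score at a p-value threshold
#'
#' Weighted sum of effect-allele dosages over the variants with
#' `p < p_threshold` (strict, per convention).  Alleles are reconciled
#' between the summary statistics and the target panel: matching order
#' uses the dosage as-is, swapped order uses `2 - dosage`, and
#' irreconcilable variants are dropped with a message.  Missing dosages
#' are imputed to `2 * effect-allele frequency`.
#'
#' @param ss clumped summary statistics.
#' @param target list with `geno` (n x m dosage of the map's `a1` allele)
#'   and `map` (with `id`, `a1`, `a2`).
#' @param p_threshold strict upper bound on `p` (e.g. one of 1e-5, .001,
#'   .01, .05, .10, .50, 1.00).
#' @return a `prs_result`: list with `raw`, `standardized` (mean 0,
#'   variance 1), `n_variants`, `p_threshold`, `dropped`.
#' @export
prs_score <- function(ss, target, p_threshold = 1) {
  use <- ss[ss$p < p_threshold, , drop = FALSE]
  mm <- match(use$snp, target$map$id)
  ok <- !is.na(mm)
  use <- use[ok, , drop = FALSE]; mm <- mm[ok]
  if (!nrow(use)) stopf("zero variants below the threshold")
  ta1 <- target$map$a1[mm]; ta2 <- target$map$a2[mm]
  same <- use$a1 == ta1 & use$a2 == ta2
  flip <- use$a1 == ta2 & use$a2 == ta1
  bad <- !(same | flip)
  if (any(bad)) message(sum(bad), " variant(s) with irreconcilable alleles; dropped")
  use <- use[!bad, , drop = FALSE]; mm <- mm[!bad]
  same <- same[!bad]
  D <- target$geno[, mm, drop = FALSE]
  if (anyNA(D)) {
    # fill on the target's a1 orientation; flipping happens below
    fill <- ifelse(same, 2 * use$freq, 2 * (1 - use$freq))
    for (j in which(colSums(is.na(D)) > 0))
      D[is.na(D[, j]), j] <- fill[j]
  }
  # a1-dosage of the sumstats effect allele
  D[, !same] <- 2 - D[, !same]
  raw <- as.vector(D %*% use$beta)
  s <- sd(raw)
  std <- if (s > 0) (raw - mean(raw)) / s else raw * 0
  structure(list(raw = raw, standardized = std,
                 n_variants = nrow(use), p_threshold = p_threshold,
                 dropped = sum(bad)),
            class = "prs_result")
}

#' Symptom-scale scores from item responses
#'
#' ADHD-inventory scales are item sums (full scale range 0-19, inattention
#' 0-9, hyperactivity 0-10); eating-disorder-inventory scales are item
#' means (range 1-6).  Legal responses: `{0, 0.5, 1}` and `{1..6}`
#' respectively.
#'
#' @param items item-response matrix with the generator's column names
#'   (`inatt1..9`, `hyp1..10` or `dt1..7`, `bul1..7`, `bd1..8`), or any
#'   matrix whose columns are all used.
#' @param scale one of `"atac_full"`, `"atac_inattention"`,
#'   `"atac_hyperactivity"`, `"edi_full"`, `"edi_dt"`, `"edi_bulimia"`,
#'   `"edi_bd"`.
#' @param missing `"complete"` (NA score if any item missing) or
#'   `"available"` (use available items; sums rescaled to the full item
#'   count).
#' @return numeric score vector.
#' @export
scale_scores <- function(items, scale = c("atac_full", "atac_inattention",
                                          "atac_hyperactivity", "edi_full",
                                          "edi_dt", "edi_bulimia", "edi_bd"),
                         missing = c("complete", "available")) {
  scale <- match.arg(scale)
  missing <- match.arg(missing)
  fam <- if (startsWith(scale, "atac")) "atac" else "edi"
  legal <- if (fam == "atac") c(0, 0.5, 1) else 1:6
  sel <- switch(scale,
    atac_full = c(paste0("inatt", 1:9), paste0("hyp", 1:10)),
    atac_inattention = paste0("inatt", 1:9),
    atac_hyperactivity = paste0("hyp", 1:10),
    edi_full = c(paste0("dt", 1:7), paste0("bul", 1:7), paste0("bd", 1:8)),
    edi_dt = paste0("dt", 1:7),
    edi_bulimia = paste0("bul", 1:7),
    edi_bd = paste0("bd", 1:8))
  if (!is.null(colnames(items)) && all(sel %in% colnames(items)))
    items <- items[, sel, drop = FALSE]
  vals <- items[!is.na(items)]
  if (!all(vals %in% legal))
    stopf("out-of-range response for scale family '%s'", fam)
  if (missing == "complete") {
    full <- complete.cases(items)
    out <- rep(NA_real_, nrow(items))
    if (fam == "atac") out[full] <- rowSums(items[full, , drop = FALSE])
    else out[full] <- rowMeans(items[full, , drop = FALSE])
  } else {
    if (fam == "atac")
      out <- rowMeans(items, na.rm = TRUE) * ncol(items)
    else out <- rowMeans(items, na.rm = TRUE)
    out[!rowSums(!is.na(items))] <- NA_real_
  }
  out
}

#' Cronbach's alpha
#'
#' Standardized variant from the mean inter-item correlation
#' `alpha = k * rbar / (1 + (k-1) * rbar)`; raw variant from item
#' variances.  Zero-variance items are excluded with a warning in the
#' standardized variant.
#'
#' @param items item-response matrix (>= 2 columns).
#' @param standardized use the mean-correlation form (default) or the
#'   variance form.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items, standardized = TRUE) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stopf("need at least two items")
  items <- items[complete.cases(items), , drop = FALSE]
  if (standardized) {
    v <- apply(items, 2, var)
    if (any(v == 0)) {
      warning("zero-variance item(s) excluded from standardized alpha")
      items <- items[, v > 0, drop = FALSE]
      if (ncol(items) < 2L) stopf("fewer than two items with variance")
    }
    k <- ncol(items)
    Rm <- cor(items)
    rbar <- mean(Rm[lower.tri(Rm)])
    k * rbar / (1 + (k - 1) * rbar)
  } else {
    k <- ncol(items)
    k / (k - 1) * (1 - sum(apply(items, 2, var)) / var(rowSums(items)))
  }
}

#' Clustered linear association of a polygenic score with a symptom scale
#'
#' Independence-working-correlation GEE for a linear model: point
#' estimates equal ordinary least squares; standard errors are
#' cluster-robust (sandwich, stacked by `clusters`, typically twin-pair
#' id), reducing to heteroskedasticity-robust SEs for singleton clusters.
#' `delta_r2` is the difference in (unadjusted) R-squared between the
#' full model and the nested model without the score; with a standardized
#' score, `beta` is the change in the symptom score per SD of the score.
#'
#' @param outcome numeric symptom-scale score.
#' @param prs numeric (typically standardized) polygenic score.
#' @param covariates data.frame/matrix of adjusters (sex, birth year,
#'   principal components, ...).
#' @param clusters cluster id vector.
#' @return list with `beta`, `se`, `ci`, `p`, `delta_r2`, `n`,
#'   `n_clusters`, the two fitted models.
#' @export
gee_linear <- function(outcome, prs, covariates = NULL, clusters = NULL) {
  ok <- complete.cases(outcome, prs)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    ok <- ok & complete.cases(covariates)
  }
  y <- outcome[ok]; x <- prs[ok]
  cl <- if (is.null(clusters)) seq_along(y) else clusters[ok]
  df <- data.frame(.y = y, prs = x)
  df0 <- data.frame(.y = y)
  if (!is.null(covariates)) {
    cv <- covariates[ok, , drop = FALSE]
    qrk <- qr(cbind(1, as.matrix(cv)))
    if (qrk$rank < ncol(cv) + 1L)
      warning("rank-deficient covariates: ", ncol(cv) + 1L - qrk$rank,
              " redundant column(s)")
    df <- cbind(df, cv); df0 <- cbind(df0, cv)
  }
  full <- lm(.y ~ ., data = df)
  nested <- lm(.y ~ ., data = df0)
  Vs <- sandwich::vcovCL(full, cluster = cl)
  b <- coef(full)[["prs"]]
  se <- sqrt(Vs["prs", "prs"])
  r2 <- function(m) summary(m)$r.squared
  list(beta = b, se = se,
       ci = c(b - 1.96 * se, b + 1.96 * se),
       p = 2 * pnorm(-abs(b / se)),
       delta_r2 = r2(full) - r2(nested),
       n = length(y), n_clusters = length(unique(cl)),
       full = full, nested = nested)
}
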