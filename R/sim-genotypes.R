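# Simulated diallelic panel with block LD, a discovery GWAS on one sample
# and genotypes for a disjoint target cohort.  Haplotypes are binary Markov
# chains within LD blocks, so the nominal adjacent allelic correlation is
# realized exactly (a thresholded-copula construction would attenuate it).

# one haplotype matrix (n x m) given per-variant freq and block structure
sim_haplotypes <- function(n, freq, block_id, r) {
  m <- length(freq)
  H <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    p <- freq[j]
    if (j == 1L || block_id[j] != block_id[j - 1L]) {
      H[, j] <- rbinom(n, 1L, p)
    } else {
      prev <- H[, j - 1L]
      # stationary two-state chain: P(1|1) = p + r(1-p), P(1|0) = p(1-r)
      pr <- ifelse(prev == 1L, p + r * (1 - p), p * (1 - r))
      H[, j] <- rbinom(n, 1L, pr)
    }
  }
  H
}

#' Simulate target genotypes and discovery GWAS summary statistics
#'
#' Builds a diallelic panel per a [geno_panel_spec()]: per-block minor
#' allele frequencies drawn from the spec range, haplotypes as binary
#' Markov chains with the spec's adjacent within-block correlation, and
#' dosages as the sum of two independent haplotypes (Hardy-Weinberg).
#' A polygenic trait with `h2` explained by `n_causal` variants is
#' simulated in a discovery sample disjoint from the target cohort;
#' per-variant marginal regressions provide the summary statistics.
#' The target cohort's true aggregate genetic values are returned so
#' downstream recovery can be tested.
#'
#' @param spec a [geno_panel_spec()].
#' @param seed integer seed.
#' @return list with components `sumstats` (data.frame: `snp`, `chr`,
#'   `pos`, `a1`, `a2`, `beta`, `se`, `p`, `freq`, `info`), `target`
#'   (list `geno` = n x m dosage matrix of the a1 allele, `map` =
#'   variant data.frame), `g_true` (target genetic values, variance
#'   `h2`) and `causal` (indices and true effects).
#' @export
simulate_genotypes_and_sumstats <- function(spec, seed = 20191015) {
  stopifnot(inherits(spec, "geno_panel_spec"))
  local_seed_if(seed)
  m <- spec$n_variants
  block_id <- rep(seq_len(ceiling(m / spec$block_length)),
                  each = spec$block_length)[seq_len(m)]
  freq <- runif(max(block_id), spec$maf_range[1], spec$maf_range[2])[block_id]

  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, m, TRUE)
  a2 <- vapply(a1, function(x) sample(setdiff(alleles, x), 1L), "")
  map <- data.frame(id = sprintf("rs%06d", seq_len(m)),
                    chr = 1L, pos = spec$bp_spacing * seq_len(m),
                    a1 = a1, a2 = unname(a2), stringsAsFactors = FALSE)

  causal <- sort(sample.int(m, spec$n_causal))
  b <- rnorm(spec$n_causal)
  b <- b * sqrt(spec$h2 / max(sum(b^2), 1e-12))   # on standardized dosages

  gvalue <- function(D) {
    Dc <- D[, causal, drop = FALSE]
    sdv <- sqrt(2 * freq[causal] * (1 - freq[causal]))
    sweep(Dc, 2, 2 * freq[causal], "-") %*% (b / sdv)
  }

  # discovery sample: marginal per-variant regressions
  Dd <- sim_haplotypes(spec$n_discovery, freq, block_id, spec$block_r) +
    sim_haplotypes(spec$n_discovery, freq, block_id, spec$block_r)
  yd <- as.vector(gvalue(Dd)) + rnorm(spec$n_discovery, sd = sqrt(1 - spec$h2))
  n <- spec$n_discovery
  Dc <- sweep(Dd, 2, colMeans(Dd), "-")
  yc <- yd - mean(yd)
  sxx <- colSums(Dc^2)
  sxx[sxx == 0] <- NA_real_
  beta <- colSums(Dc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(rss / ((n - 2) * sxx))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - 2)
  pval[is.na(pval)] <- 1
  beta[is.na(beta)] <- 0

  info <- rbeta(m, 30, 2)                 # imputation-quality-like in (0,1)
  sumstats <- data.frame(snp = map$id, chr = map$chr, pos = map$pos,
                         a1 = map$a1, a2 = map$a2,
                         beta = beta, se = se, p = pmax(pval, 1e-300),
                         freq = colMeans(Dd) / 2, info = info,
                         stringsAsFactors = FALSE)

  Dt <- sim_haplotypes(spec$n_target, freq, block_id, spec$block_r) +
    sim_haplotypes(spec$n_target, freq, block_id, spec$block_r)
  list(sumstats = sumstats,
       target = list(geno = Dt, map = map),
       g_true = as.vector(gvalue(Dt)),
       causal = list(index = causal, beta = b))
}
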