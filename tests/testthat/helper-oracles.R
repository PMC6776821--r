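# Independent brute-force oracles used across the suite.  These are kept
# deliberately naive (O(n^2) scans, direct rule checks) so they cannot
# share a defect with the implementation paths they validate.

# exhaustive relative-pair scan over every individual pair, using only
# parent links; returns counts per class
oracle_pair_counts <- function(ped) {
  off <- ped[ped$offspring, , drop = FALSE]
  n <- nrow(off)
  parent_of <- function(id) {
    k <- match(id, ped$iid)
    c(ped$mid[k], ped$pid[k])
  }
  full_sibs <- function(x, y) {
    if (is.na(x) || is.na(y) || x == y) return(FALSE)
    px <- parent_of(x); py <- parent_of(y)
    !anyNA(px) && !anyNA(py) && px[1] == py[1] && px[2] == py[2]
  }
  counts <- c(full_sibling = 0, maternal_half_sibling = 0,
              paternal_half_sibling = 0, cousin = 0)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ma <- off$mid[a]; pa <- off$pid[a]
    mb <- off$mid[b]; pb <- off$pid[b]
    sm <- !is.na(ma) && !is.na(mb) && ma == mb
    sp <- !is.na(pa) && !is.na(pb) && pa == pb
    if (sm && sp) counts["full_sibling"] <- counts["full_sibling"] + 1
    else if (sm) counts["maternal_half_sibling"] <-
        counts["maternal_half_sibling"] + 1
    else if (sp) counts["paternal_half_sibling"] <-
        counts["paternal_half_sibling"] + 1
    else if (full_sibs(ma, mb) || full_sibs(ma, pb) ||
             full_sibs(pa, mb) || full_sibs(pa, pb))
      counts["cousin"] <- counts["cousin"] + 1
  }
  counts
}

# check a clumping result against the greedy rule itself: every retained
# variant must be uncorrelated (<= r2_max) with every smaller-p retained
# variant inside the window, and every removed variant must be within the
# window of, and correlated (> r2_max) with, some smaller-p retained one
oracle_clump_valid <- function(ss, kept_ids, reference, r2_max, window_kb) {
  G <- reference$geno[, match(ss$snp, reference$map$id), drop = FALSE]
  kept <- ss$snp %in% kept_ids
  win <- window_kb * 1000
  r2 <- function(i, j) {
    r <- suppressWarnings(cor(G[, i], G[, j]))
    if (is.na(r)) 0 else r^2
  }
  for (j in which(kept)) {
    for (i in which(kept)) {
      if (ss$p[i] < ss$p[j] || (ss$p[i] == ss$p[j] && ss$snp[i] < ss$snp[j])) {
        if (ss$chr[i] == ss$chr[j] && abs(ss$pos[i] - ss$pos[j]) <= win &&
            r2(i, j) > r2_max) return(FALSE)
      }
    }
  }
  for (k in which(!kept)) {
    hit <- FALSE
    for (i in which(kept)) {
      if ((ss$p[i] < ss$p[k] || (ss$p[i] == ss$p[k] && ss$snp[i] < ss$snp[k])) &&
          ss$chr[i] == ss$chr[k] && abs(ss$pos[i] - ss$pos[k]) <= win &&
          r2(i, k) > r2_max) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# small random PSD correlation matrix
random_corr <- function(d, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) + diag(d) * 0.5
    D <- diag(1 / sqrt(diag(S)))
    D %*% S %*% D
  })
}

# default bivariate architecture used in several tests
test_arch <- function(a2 = c(.82, .45), rA = .37, rE = .15,
                      prev = c(.022, .01)) {
  architecture_spec(a2 = a2, rA = rA, rE = rE, prevalence = prev,
                    traits = c("x", "y"))
}
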