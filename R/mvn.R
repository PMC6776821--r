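# Deterministic multivariate-normal rectangle probabilities for the
# liability-threshold likelihoods.  Everything here is vectorized because a
# single bivariate model fit evaluates ~10^3 bivariate CDFs per likelihood
# call; scalar CDF routines would dominate the runtime.

# -- Gauss-Legendre nodes/weights on [0, 1], cached per order ---------------
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre01 <- function(n) {
  key <- as.character(n)
  got <- .gl_cache[[key]]
  if (!is.null(got)) return(got)
  j <- seq_len(n - 1L)
  b <- j / sqrt(4 * j^2 - 1)
  E <- matrix(0, n, n)
  E[cbind(j, j + 1L)] <- b
  E[cbind(j + 1L, j)] <- b
  ev <- eigen(E, symmetric = TRUE)
  out <- list(x = (ev$values + 1) / 2, w = ev$vectors[1L, ]^2)
  .gl_cache[[key]] <- out
  out
}

# Drezner-Wesolowsky angle form, accurate for |rho| <= 0.925.
pbvn_angle <- function(h, k, rho) {
  out <- pnorm(h) * pnorm(k)
  nz <- rho != 0
  if (any(nz)) {
    G <- gauss_legendre01(20L)
    a <- asin(rho[nz]); hh <- h[nz]; kk <- k[nz]
    acc <- 0
    for (i in seq_along(G$x)) {
      th <- a * G$x[i]
      acc <- acc + G$w[i] * exp(-(hh^2 + kk^2 - 2 * hh * kk * sin(th)) /
                                  (2 * cos(th)^2))
    }
    out[nz] <- out[nz] + a * acc / (2 * pi)
  }
  out
}

# Conditional 1-D quadrature P(X < h, Y < k); caller guarantees the target
# orientation has the smallest probability so the integrand stays smooth.
pbvn_cond <- function(h, k, rho) {
  n <- length(h)
  swap <- pnorm(k) < pnorm(h)
  tmp <- h[swap]; h[swap] <- k[swap]; k[swap] <- tmp
  ph <- pnorm(h)
  s <- sqrt((1 - rho) * (1 + rho))
  out <- numeric(n)
  nz <- ph > 0 & s > 0
  if (any(nz)) {
    G <- gauss_legendre01(64L)
    U <- outer(ph[nz], G$x)
    X <- qnorm(U)
    A <- (k[nz] - rho[nz] * X) / s[nz]
    out[nz] <- ph[nz] * as.vector(pnorm(A) %*% G$w)
  }
  dg <- s == 0 & ph > 0
  if (any(dg)) {
    out[dg] <- ifelse(rho[dg] > 0,
                      pmin(ph, pnorm(k))[dg],
                      pmax(0, ph + pnorm(k) - 1)[dg])
  }
  out
}

#' Bivariate standard-normal CDF
#'
#' `P(X < h, Y < k)` for standard bivariate normal variables with
#' correlation `rho`; fully vectorized over all three arguments.
#' Uses an angle-form Gauss-Legendre quadrature for moderate correlations
#' and a smallest-orientation conditional reduction near `|rho| = 1`;
#' absolute accuracy is better than 1e-9 over `|rho| <= 0.999`.
#'
#' @param h,k upper integration limits (recycled to common length).
#' @param rho correlation(s) in `[-1, 1]`.
#' @return vector of probabilities.
#' @export
pbvn <- function(h, k, rho) {
  n <- max(length(h), length(k), length(rho))
  h <- pmax(pmin(rep_len(h, n), 8.5), -8.5)
  k <- pmax(pmin(rep_len(k, n), 8.5), -8.5)
  rho <- rep_len(rho, n)
  if (any(abs(rho) > 1)) stopf("correlation outside [-1, 1]")
  out <- numeric(n)
  lo <- abs(rho) <= 0.925
  if (any(lo)) out[lo] <- pbvn_angle(h[lo], k[lo], rho[lo])
  if (any(!lo)) {
    hh <- h[!lo]; kk <- k[!lo]; r <- rho[!lo]
    # choose, among the four equivalent rectangles, the one with the
    # smallest probability; reconstruct by inclusion-exclusion
    est <- cbind(pmin(pnorm(hh), pnorm(kk)),
                 pmin(pnorm(-hh), pnorm(kk)),
                 pmin(pnorm(hh), pnorm(-kk)),
                 pmin(pnorm(-hh), pnorm(-kk)))
    pick <- max.col(-est, ties.method = "first")
    v <- numeric(length(hh))
    i <- pick == 1L
    if (any(i)) v[i] <- pbvn_cond(hh[i], kk[i], r[i])
    i <- pick == 2L
    if (any(i)) v[i] <- pnorm(kk[i]) - pbvn_cond(-hh[i], kk[i], -r[i])
    i <- pick == 3L
    if (any(i)) v[i] <- pnorm(hh[i]) - pbvn_cond(hh[i], -kk[i], -r[i])
    i <- pick == 4L
    if (any(i)) v[i] <- pnorm(hh[i]) + pnorm(kk[i]) - 1 +
      pbvn_cond(-hh[i], -kk[i], r[i])
    out[!lo] <- v
  }
  pmin(pmax(out, 0), 1)
}

# rectangle P(l < X < u) under correlation matrix R, dimensions 1-4.
# 3- and 4-dim cases reduce to conditional bivariate rectangles integrated
# over truncated outer variables (inverse-CDF transformed Gauss-Legendre).
pmvn_rect <- function(lower, upper, R, n_nodes = 96L) {
  d <- length(lower)
  if (length(upper) != d) stopf("lower/upper length mismatch")
  if (any(upper < lower)) stopf("upper < lower")
  if (d == 1L) return(pnorm(upper) - pnorm(lower))
  R <- as.matrix(R)
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, d), tolerance = 1e-8)))
    stopf("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("correlation matrix is not positive semi-definite")
  if (d == 2L) {
    return(pbvn(upper[1], upper[2], R[1, 2]) -
             pbvn(lower[1], upper[2], R[1, 2]) -
             pbvn(upper[1], lower[2], R[1, 2]) +
             pbvn(lower[1], lower[2], R[1, 2]))
  }
  G <- gauss_legendre01(n_nodes)
  if (d == 3L) {
    p_lo <- pnorm(lower[1]); p_hi <- pnorm(upper[1])
    len <- p_hi - p_lo
    if (len <= 0) return(0)
    x1 <- qnorm(p_lo + G$x * len)
    S11 <- R[1, 1, drop = FALSE]
    B <- R[2:3, 1, drop = FALSE]            # conditional slope
    Cc <- R[2:3, 2:3] - B %*% t(B)
    s2 <- sqrt(Cc[1, 1]); s3 <- sqrt(Cc[2, 2])
    rc <- Cc[1, 2] / (s2 * s3)
    m2 <- B[1] * x1; m3 <- B[2] * x1
    p <- pbvn((upper[2] - m2) / s2, (upper[3] - m3) / s3, rc) -
      pbvn((lower[2] - m2) / s2, (upper[3] - m3) / s3, rc) -
      pbvn((upper[2] - m2) / s2, (lower[3] - m3) / s3, rc) +
      pbvn((lower[2] - m2) / s2, (lower[3] - m3) / s3, rc)
    return(len * sum(G$w * p))
  }
  if (d == 4L) {
    p_lo1 <- pnorm(lower[1]); len1 <- pnorm(upper[1]) - p_lo1
    if (len1 <= 0) return(0)
    x1 <- qnorm(p_lo1 + G$x * len1)
    w1 <- G$w * len1
    r12 <- R[1, 2]
    s2 <- sqrt(1 - r12^2)
    m2 <- r12 * x1
    a_lo <- pnorm((lower[2] - m2) / s2)
    a_hi <- pnorm((upper[2] - m2) / s2)
    len2 <- a_hi - a_lo                      # per outer node
    S11 <- R[1:2, 1:2]
    B <- R[3:4, 1:2] %*% solve(S11)
    Cc <- R[3:4, 3:4] - R[3:4, 1:2] %*% solve(S11) %*% R[1:2, 3:4]
    s3 <- sqrt(Cc[1, 1]); s4 <- sqrt(Cc[2, 2])
    rc <- Cc[1, 2] / (s3 * s4)
    n1 <- length(x1); n2 <- length(G$x)
    V <- outer(len2, G$x) + a_lo             # n1 x n2 conditional quantiles
    X2 <- m2 + s2 * qnorm(V)
    X1 <- matrix(x1, n1, n2)
    W <- outer(w1 * len2, G$w)
    M <- cbind(as.vector(X1), as.vector(X2)) %*% t(B)
    a3u <- (upper[3] - M[, 1]) / s3; a3l <- (lower[3] - M[, 1]) / s3
    a4u <- (upper[4] - M[, 2]) / s4; a4l <- (lower[4] - M[, 2]) / s4
    p <- pbvn(a3u, a4u, rc) - pbvn(a3l, a4u, rc) -
      pbvn(a3u, a4l, rc) + pbvn(a3l, a4l, rc)
    return(sum(as.vector(W) * pmax(p, 0)))
  }
  stopf("dimensions above 4 are not supported")
}

#' Orthant probability of a thresholded multivariate normal
#'
#' Probability that each coordinate of a zero-mean multivariate normal with
#' correlation matrix `R` falls on the stated side of its threshold:
#' `signs[i] = +1` means above `thresholds[i]`, `-1` means below.
#' Supports 2-4 dimensions via deterministic quadrature (no Monte Carlo);
#' the probabilities over all `2^d` sign patterns sum to 1 within 1e-6.
#'
#' @param R correlation matrix (unit diagonal, positive semi-definite).
#' @param thresholds numeric vector of thresholds, one per dimension.
#' @param signs vector of `+1`/`-1` (or `">"`/`"<"`), one per dimension.
#' @return scalar probability.
#' @examples
#' R <- diag(2)
#' orthant_probability(R, c(0, 0), c(1, 1))  # 0.25 under independence
#' @export
orthant_probability <- function(R, thresholds, signs) {
  d <- length(thresholds)
  if (is.character(signs)) signs <- ifelse(signs == ">", 1, -1)
  if (length(signs) != d) stopf("signs/thresholds length mismatch")
  lower <- ifelse(signs > 0, thresholds, -Inf)
  upper <- ifelse(signs > 0, Inf, thresholds)
  pmvn_rect(lower, upper, R)
}

# All 16 cell probabilities of a thresholded 4-dim liability vector
# (sister1 trait X, sister1 trait Y, sister2 trait X, sister2 trait Y).
# Returned array dims: [x1, y1, x2, y2], level 1 = below threshold
# (unaffected), level 2 = above (affected).  Shares outer quadrature nodes
# across cells, so one call costs four vectorized pbvn evaluations.
pair_cell_probs <- function(R, t_x, t_y, n_nodes = 16L) {
  G <- gauss_legendre01(n_nodes)
  S11 <- R[1:2, 1:2]
  det11 <- S11[1, 1] * S11[2, 2] - S11[1, 2] * S11[2, 1]
  if (det11 < 1e-10)
    stopf("degenerate within-member correlation block (|r| ~ 1)")
  iS11 <- matrix(c(S11[2, 2], -S11[1, 2], -S11[2, 1], S11[1, 1]),
                 2) / det11
  B <- R[3:4, 1:2] %*% iS11
  Cc <- R[3:4, 3:4] - R[3:4, 1:2] %*% iS11 %*% R[1:2, 3:4]
  s3 <- sqrt(Cc[1, 1]); s4 <- sqrt(Cc[2, 2])
  rc <- Cc[1, 2] / (s3 * s4)
  r12 <- R[1, 2]
  s2 <- sqrt(1 - r12^2)
  cells <- array(0, c(2, 2, 2, 2))
  Ptx <- pnorm(t_x)
  n1 <- n_nodes; n2 <- n_nodes
  for (q1 in 0:1) {                        # sister1 trait X: 0 below, 1 above
    lo1 <- if (q1 == 0) 0 else Ptx
    len1 <- if (q1 == 0) Ptx else 1 - Ptx
    if (len1 <= 0) next
    x1 <- qnorm(lo1 + G$x * len1)
    w1 <- G$w * len1
    m2 <- r12 * x1
    P2 <- pnorm((t_y - m2) / s2)
    for (q2 in 0:1) {                      # sister1 trait Y
      lo2 <- if (q2 == 0) 0 else P2
      len2 <- if (q2 == 0) P2 else 1 - P2
      V <- outer(len2, G$x) + lo2
      X2 <- m2 + s2 * qnorm(V)
      X1 <- matrix(x1, n1, n2)
      W <- as.vector(outer(w1 * len2, G$w))
      M <- cbind(as.vector(X1), as.vector(X2)) %*% t(B)
      a3 <- (t_x - M[, 1]) / s3
      a4 <- (t_y - M[, 2]) / s4
      p11 <- pbvn(a3, a4, rc)
      p1 <- pnorm(a3); p2 <- pnorm(a4)
      cells[q1 + 1, q2 + 1, 1, 1] <- sum(W * p11)
      cells[q1 + 1, q2 + 1, 1, 2] <- sum(W * (p1 - p11))
      cells[q1 + 1, q2 + 1, 2, 1] <- sum(W * (p2 - p11))
      cells[q1 + 1, q2 + 1, 2, 2] <- sum(W * (1 - p1 - p2 + p11))
    }
  }
  pmax(cells, 0)
}

# univariate analogue: P(both affected), P(both unaffected), P(discordant)
# for one trait in a sibling pair with cross-sibling liability corr r.
uni_pair_probs <- function(r, t) {
  both_un <- pbvn(t, t, r)
  p_un <- pnorm(t)
  both_aff <- 1 - 2 * p_un + both_un
  disc <- 2 * (p_un - both_un)
  c(both_affected = pmax(both_aff, 0),
    both_unaffected = pmax(both_un, 0),
    discordant = pmax(disc, 0))
}
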