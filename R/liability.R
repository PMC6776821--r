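# Liability-threshold quantitative genetics: tetrachoric correlation MLE,
# and univariate/bivariate ACE/ADE/AE variance decompositions fitted by
# maximum likelihood to pair contingency tables from multiple relative
# classes, with AIC selection and delta-method CIs for the derived
# heritability, coheritability and genetic correlation.

#' Liability threshold from prevalence
#'
#' The diagnostic threshold on the standard-normal liability scale:
#' `Phi(threshold) = 1 - prevalence`.
#'
#' @param prevalence prevalence(s) in (0, 1).
#' @return standard-normal quantile(s).
#' @export
threshold_from_prevalence <- function(prevalence) {
  if (any(prevalence <= 0 | prevalence >= 1))
    stopf("prevalence must lie strictly in (0, 1)")
  qnorm(1 - prevalence)
}

#' Tetrachoric correlation by maximum likelihood
#'
#' Estimates the correlation of two latent bivariate-normal variables from
#' the 2x2 table of their dichotomized versions.  Thresholds are fixed at
#' the margins' normal quantiles; the correlation maximizes the
#' multinomial likelihood of the four cells (fractional counts allowed).
#' Standard errors come from the observed information; estimates within
#' 0.002 of the boundary are flagged.
#'
#' @param tab 2x2 numeric matrix (rows: variable 1 unaffected/affected,
#'   columns: variable 2) or a one-trait `pair_count_table`.
#' @return list with `rho`, `se`, `ci` (95%), `thresholds`, `loglik`,
#'   `boundary`, `n`.
#' @export
tetrachoric_mle <- function(tab) {
  if (inherits(tab, "pair_count_table")) {
    if (is.null(tab$table)) stopf("two-trait tables: use fit_bivariate")
    tab <- tab$table
  }
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L) || any(tab < 0)) stopf("need a 2x2 count table")
  n <- sum(tab)
  if (n <= 0) stopf("empty table")
  p1 <- sum(tab[2, ]) / n
  p2 <- sum(tab[, 2]) / n
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stopf("zero margin: tetrachoric correlation undefined")
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  nll <- function(r) {
    F00 <- pbvn(t1, t2, r)
    p <- c(F00, pnorm(t1) - F00, pnorm(t2) - F00,
           1 - pnorm(t1) - pnorm(t2) + F00)
    p <- pmax(p, 1e-300)
    -(tab[1, 1] * log(p[1]) + tab[1, 2] * log(p[2]) +
        tab[2, 1] * log(p[3]) + tab[2, 2] * log(p[4]))
  }
  opt <- optimize(nll, c(-0.999, 0.999), tol = 1e-9)
  rho <- opt$minimum
  h <- tryCatch(numDeriv::hessian(nll, rho)[1, 1], error = function(e) NA)
  se <- if (is.finite(h) && h > 0) 1 / sqrt(h) else NA_real_
  boundary <- abs(rho) > 0.997
  list(rho = rho, se = se,
       ci = c(max(-1, rho - 1.96 * se), min(1, rho + 1.96 * se)),
       thresholds = c(t1, t2), loglik = -opt$objective,
       boundary = boundary, n = n)
}

#' Expected pair liability correlation matrix
#'
#' The 4x4 correlation matrix of (member-1 trait X, member-1 trait Y,
#' member-2 trait X, member-2 trait Y) implied by a variance-component set
#' and a relative class: within-individual cross-trait entries are
#' `covA + covD + covC + covE`; cross-member same-trait entries are
#' `kA*a2 + kD*d2 + kC*c2`; cross-member cross-trait entries are
#' `kA*covA + kD*covD + kC*covC`.
#'
#' @param vc an [architecture_spec()] or any list with fields `a2`, `d2`,
#'   `c2`, `e2` (length 2) and `covA`, `covD`, `covC`, `covE`.
#' @param class a [relatedness_class()] or class label.
#' @return 4x4 correlation matrix (unit diagonal).
#' @export
pair_model_matrix <- function(vc, class) {
  cl <- as_relatedness_class(class)
  rp <- vc$covA + vc$covD + vc$covC + vc$covE     # within-person cross-trait
  cx <- cl$kA * vc$a2 + cl$kD * vc$d2 + cl$kC * vc$c2  # same trait, per trait
  cc <- cl$kA * vc$covA + cl$kD * vc$covD + cl$kC * vc$covC
  W <- matrix(c(1, rp, rp, 1), 2)
  X <- matrix(c(cx[1], cc, cc, cx[2]), 2)
  R <- rbind(cbind(W, X), cbind(t(X), W))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("implied pair matrix is not positive semi-definite")
  R
}

# ---- internal helpers shared by the ML fits --------------------------------

# variance-parameter transform: unconstrained vector -> component set
vc_from_par <- function(vp, model) {
  if (model == "AE") {
    a2 <- plogis(vp[1:2]); o2 <- c(0, 0)
    rA <- tanh(vp[3]); rO <- 0; rE <- tanh(vp[4])
  } else {
    sm <- function(la, lo) {
      z <- exp(c(la, lo, 0)); z / sum(z)
    }
    s1 <- sm(vp[1], vp[2]); s2 <- sm(vp[3], vp[4])
    a2 <- c(s1[1], s2[1]); o2 <- c(s1[2], s2[2])
    rA <- tanh(vp[5]); rO <- tanh(vp[6]); rE <- tanh(vp[7])
  }
  e2 <- pmax(1 - a2 - o2, 0)
  d2 <- c2 <- c(0, 0)
  covD <- covC <- 0
  if (model == "ADE") { d2 <- o2; covD <- rO * sqrt(prod(d2)) }
  if (model == "ACE") { c2 <- o2; covC <- rO * sqrt(prod(c2)) }
  list(a2 = a2, d2 = d2, c2 = c2, e2 = e2,
       covA = rA * sqrt(prod(a2)), covD = covD, covC = covC,
       covE = rE * sqrt(prod(e2)),
       rA = rA, rO = rO, rE = rE)
}

n_varpar <- function(model) if (model == "AE") 4L else 7L

as_cells <- function(x) {
  if (inherits(x, "pair_count_table")) {
    if (is.null(x$cells)) stopf("expected a two-trait 16-cell table")
    x$cells
  } else if (is.array(x) && all(dim(x) == c(2, 2, 2, 2))) x
  else stopf("expected a 2x2x2x2 cell array")
}

as_triplet <- function(x) {
  if (inherits(x, "pair_count_table")) {
    if (!is.null(x$cells)) {
      # collapse a 16-cell table over the second trait
      cells <- x$cells
      m <- apply(cells, c(1, 3), sum)
      c(both_affected = m[2, 2], both_unaffected = m[1, 1],
        discordant = m[1, 2] + m[2, 1])
    } else {
      c(both_affected = x$both_affected, both_unaffected = x$both_unaffected,
        discordant = x$discordant)
    }
  } else if (is.numeric(x) && length(x) == 3L) {
    setNames(x, c("both_affected", "both_unaffected", "discordant"))
  } else stopf("expected counts (both_affected, both_unaffected, discordant)")
}

#' Univariate liability model fitted jointly across relative classes
#'
#' Fits the single-trait A(C/D)E liability-threshold model by maximum
#' likelihood to the (both affected / both unaffected / discordant) pair
#' counts of two or more relative classes simultaneously.  Cross-member
#' liability correlation for class `c` is `kA_c*a2 + kD_c*d2 + kC_c*c2`.
#' Thresholds are estimated per relative class by default (classes drawn
#' from strata with different observed margins), or shared.
#'
#' @param tables named list (names = relative class labels) of one-trait
#'   `pair_count_table`s or length-3 count vectors
#'   `(both_affected, both_unaffected, discordant)`.
#' @param model `"AE"`, `"ACE"` or `"ADE"`.
#' @param thresholds `"by_class"` or `"shared"`.
#' @return a `univariate_fit`: estimates with delta-method CIs, loglik,
#'   AIC, parameter covariance, convergence status.
#' @export
fit_univariate <- function(tables, model = c("AE", "ACE", "ADE"),
                           thresholds = c("by_class", "shared")) {
  model <- match.arg(model)
  thresholds <- match.arg(thresholds)
  if (length(tables) < 2L)
    stopf("need >= 2 relative classes with differing coefficients")
  classes <- lapply(names(tables), relatedness_class)
  cnt <- lapply(tables, as_triplet)
  C <- length(cnt)
  n_thr <- if (thresholds == "shared") 1L else C
  kv <- if (model == "AE") 1L else 2L      # variance params beyond E
  # par = thresholds, then qlogis/softmax variance fractions
  nll <- function(par) {
    th <- par[seq_len(n_thr)]
    vp <- par[-seq_len(n_thr)]
    if (model == "AE") { a2 <- plogis(vp[1]); o2 <- 0 }
    else { z <- exp(c(vp[1], vp[2], 0)); a2 <- z[1] / sum(z); o2 <- z[2] / sum(z) }
    tot <- 0
    for (ci in seq_len(C)) {
      cl <- classes[[ci]]
      r <- cl$kA * a2 +
        (if (model == "ADE") cl$kD * o2 else 0) +
        (if (model == "ACE") cl$kC * o2 else 0)
      t_c <- th[min(ci, n_thr)]
      p <- uni_pair_probs(r, t_c)
      p <- pmax(p, 1e-300)
      x <- cnt[[ci]]
      tot <- tot - (x[1] * log(p[1]) + x[2] * log(p[2]) + x[3] * log(p[3]))
    }
    tot
  }
  # starting values: margins per class; WLS over class tetrachorics
  marg <- vapply(cnt, function(x) (2 * x[1] + x[3]) / (2 * sum(x)), 0)
  th0 <- qnorm(1 - marg)
  if (thresholds == "shared")
    th0 <- qnorm(1 - sum(vapply(cnt, function(x) 2 * x[1] + x[3], 0)) /
                   (2 * sum(vapply(cnt, sum, 0))))
  rhat <- vapply(seq_len(C), function(ci) {
    tetrachoric_mle(pair_table_2x2(cnt[[ci]][1], cnt[[ci]][2],
                                   cnt[[ci]][3]))$rho
  }, 0)
  w <- vapply(cnt, sum, 0)
  kA <- vapply(classes, function(cl) cl$kA, 0)
  a2_0 <- min(max(sum(w * kA * rhat) / sum(w * kA^2), 0.05), 0.95)
  vp0 <- if (model == "AE") qlogis(a2_0)
         else c(log(a2_0 / max(1 - a2_0 - 0.1, .05)), log(0.1 / max(1 - a2_0 - 0.1, .05)))
  par0 <- c(th0, vp0)
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-12))
  H <- numDeriv::hessian(nll, opt$par)
  Vp <- tryCatch(solve(H), error = function(e) matrix(NA, length(par0),
                                                      length(par0)))
  th <- opt$par[seq_len(n_thr)]
  vp <- opt$par[-seq_len(n_thr)]
  derive <- function(par) {
    v <- par[-seq_len(n_thr)]
    if (model == "AE") {
      a2 <- plogis(v[1]); o2 <- 0
    } else {
      z <- exp(c(v[1], v[2], 0)); a2 <- z[1] / sum(z); o2 <- z[2] / sum(z)
    }
    c(a2 = a2, o2 = o2, e2 = 1 - a2 - o2)
  }
  est <- derive(opt$par)
  J <- numDeriv::jacobian(derive, opt$par)
  Vd <- J %*% Vp %*% t(J)
  se <- sqrt(pmax(diag(Vd), 0))
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  other <- switch(model, AE = NULL, ACE = "c2", ADE = "d2")
  nm <- c("a2", other %||% "o2", "e2")
  structure(list(
    model = model, thresholds_mode = thresholds,
    estimates = setNames(est, nm),
    se = setNames(se, nm),
    ci = matrix(ci, ncol = 2, dimnames = list(nm, c("lo", "hi"))),
    thresholds = setNames(th, if (n_thr == 1L) "shared" else names(tables)),
    loglik = -opt$value, k = length(par0),
    AIC = 2 * opt$value + 2 * length(par0),
    vcov_par = Vp, convergence = opt$convergence,
    classes = names(tables)),
    class = "univariate_fit")
}

#' @export
print.univariate_fit <- function(x, ...) {
  cat(sprintf("univariate %s liability fit (%s)\n", x$model,
              paste(x$classes, collapse = " + ")))
  for (nm in names(x$estimates))
    cat(sprintf("  %s = %.3f (95%% CI %.3f, %.3f)\n", nm, x$estimates[nm],
                x$ci[nm, 1], x$ci[nm, 2]))
  cat(sprintf("  loglik %.2f, AIC %.2f, k=%d\n", x$loglik, x$AIC, x$k))
  invisible(x)
}

#' Bivariate liability model fitted jointly across relative classes
#'
#' Maximum-likelihood fit of the bivariate ACE, ADE or AE
#' liability-threshold model to 16-cell pair tables from two or more
#' relative classes with differing sharing coefficients.  Cross-trait
#' component matrices are parameterized by per-trait fractions and a
#' component correlation (bounded via tanh), which keeps every implied
#' 4x4 pair matrix positive semi-definite.  The likelihood is the
#' (weighted, fractional-count capable) multinomial over the 16 cells,
#' symmetric in member order.  Derived quantities — heritability per
#' trait, coheritability (share of the phenotypic liability covariance
#' attributable to a component) and the genetic correlation — carry
#' delta-method 95% CIs.
#'
#' @param tables named list (names = class labels) of two-trait
#'   `pair_count_table`s or 2x2x2x2 count arrays.
#' @param model `"AE"`, `"ACE"` or `"ADE"`.
#' @param thresholds `"by_class"` (default) or `"shared"` across classes.
#' @param max_restarts jittered restarts if the optimizer fails to
#'   converge from the method-of-moments start.
#' @param seed seed for the (rarely needed) jittered restarts.
#' @return a `bivariate_fit` with components, derived quantities + CIs,
#'   loglik, AIC, convergence status.
#' @export
fit_bivariate <- function(tables, model = c("AE", "ACE", "ADE"),
                          thresholds = c("by_class", "shared"),
                          max_restarts = 2L, seed = 20191015) {
  model <- match.arg(model)
  thresholds <- match.arg(thresholds)
  if (length(tables) < 2L)
    stopf("need >= 2 relative classes with differing coefficients")
  classes <- lapply(names(tables), relatedness_class)
  cells <- lapply(tables, as_cells)
  cells <- lapply(cells, symmetrize_cells)
  C <- length(cells)
  n_thr <- if (thresholds == "shared") 2L else 2L * C
  nv <- n_varpar(model)

  nll <- function(par) {
    th <- par[seq_len(n_thr)]
    vc <- vc_from_par(par[-seq_len(n_thr)], model)
    tot <- 0
    for (ci in seq_len(C)) {
      R <- tryCatch(pair_model_matrix(vc, classes[[ci]]),
                    error = function(e) NULL)
      if (is.null(R)) return(1e10)
      ti <- if (thresholds == "shared") c(1L, 2L) else c(2L * ci - 1L, 2L * ci)
      p <- tryCatch(pair_cell_probs(R, th[ti[1]], th[ti[2]]),
                    error = function(e) NULL)
      if (is.null(p)) return(1e10)
      tot <- tot - sum(cells[[ci]] * log(pmax(p, 1e-300)))
    }
    if (!is.finite(tot)) 1e10 else tot
  }

  # method-of-moments starting values from collapsed tetrachorics
  trip_x <- lapply(cells, function(cl) as_triplet(
    structure(list(cells = cl), class = "pair_count_table")))
  trip_y <- lapply(cells, function(cl) {
    m <- apply(cl, c(2, 4), sum)
    c(m[2, 2], m[1, 1], m[1, 2] + m[2, 1])
  })
  marg_x <- vapply(trip_x, function(x) (2 * x[1] + x[3]) / (2 * sum(x)), 0)
  marg_y <- vapply(trip_y, function(x) (2 * x[1] + x[3]) / (2 * sum(x)), 0)
  th0 <- as.vector(rbind(qnorm(1 - marg_x), qnorm(1 - marg_y)))
  if (thresholds == "shared") {
    wts <- vapply(cells, sum, 0)
    th0 <- c(qnorm(1 - sum(marg_x * wts) / sum(wts)),
             qnorm(1 - sum(marg_y * wts) / sum(wts)))
  }
  safe_rho <- function(tab) tryCatch(tetrachoric_mle(tab)$rho,
                                     error = function(e) 0)
  r_x <- vapply(seq_len(C), function(ci) safe_rho(
    pair_table_2x2(trip_x[[ci]][1], trip_x[[ci]][2], trip_x[[ci]][3])), 0)
  r_y <- vapply(seq_len(C), function(ci) safe_rho(
    pair_table_2x2(trip_y[[ci]][1], trip_y[[ci]][2], trip_y[[ci]][3])), 0)
  r_cross <- vapply(seq_len(C), function(ci) {
    ct <- apply(cells[[ci]], c(1, 4), sum) + apply(cells[[ci]], c(3, 2), sum)
    safe_rho(ct)
  }, 0)
  r_phen <- vapply(seq_len(C), function(ci) {
    wp <- apply(cells[[ci]], c(1, 2), sum) + apply(cells[[ci]], c(3, 4), sum)
    safe_rho(wp)
  }, 0)
  w <- vapply(cells, sum, 0)
  kA <- vapply(classes, function(cl) cl$kA, 0)
  wls_a2 <- function(r) min(max(sum(w * kA * r) / sum(w * kA^2), 0.05), 0.9)
  a2x0 <- wls_a2(r_x); a2y0 <- wls_a2(r_y)
  covA0 <- sum(w * kA * r_cross) / sum(w * kA^2)
  phen0 <- sum(w * r_phen) / sum(w)
  rA0 <- min(max(covA0 / sqrt(a2x0 * a2y0), -0.9), 0.9)
  rE0 <- min(max((phen0 - covA0) / sqrt((1 - a2x0) * (1 - a2y0)), -0.9), 0.9)
  if (model == "AE") {
    vp0 <- c(qlogis(a2x0), qlogis(a2y0), atanh(rA0), atanh(rE0))
  } else {
    e0x <- max(1 - a2x0 - 0.1, 0.05); e0y <- max(1 - a2y0 - 0.1, 0.05)
    vp0 <- c(log(a2x0 / e0x), log(0.1 / e0x),
             log(a2y0 / e0y), log(0.1 / e0y),
             atanh(rA0), 0, atanh(rE0))
  }
  par0 <- c(th0, vp0)

  fit_once <- function(p0) optim(p0, nll, method = "BFGS",
                                 control = list(maxit = 400, reltol = 1e-12))
  opt <- fit_once(par0)
  tries <- 0L
  while (opt$convergence != 0 && tries < max_restarts) {
    tries <- tries + 1L
    local_seed_if(derive_seed(seed, tries))
    opt2 <- fit_once(par0 + rnorm(length(par0), sd = 0.2))
    if (opt2$value < opt$value) opt <- opt2
  }

  H <- numDeriv::hessian(nll, opt$par)
  Vp <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  derive <- function(par) {
    vc <- vc_from_par(par[-seq_len(n_thr)], model)
    phen <- vc$covA + vc$covD + vc$covC + vc$covE
    out <- c(a2_x = vc$a2[1], a2_y = vc$a2[2],
             e2_x = vc$e2[1], e2_y = vc$e2[2],
             covA = vc$covA, covE = vc$covE, phen_cov = phen,
             coher_A = vc$covA / phen, coher_E = vc$covE / phen,
             rg = vc$rA, re = vc$rE)
    if (model == "ACE") out <- c(out, c2_x = vc$c2[1], c2_y = vc$c2[2],
                                 covC = vc$covC, rc = vc$rO)
    if (model == "ADE") out <- c(out, d2_x = vc$d2[1], d2_y = vc$d2[2],
                                 covD = vc$covD, rd = vc$rO)
    out
  }
  est <- derive(opt$par)
  J <- numDeriv::jacobian(derive, opt$par)
  Vd <- J %*% Vp %*% t(J)
  se <- sqrt(pmax(diag(Vd), 0))
  derived <- data.frame(estimate = est, se = se,
                        lo = est - 1.96 * se, hi = est + 1.96 * se)
  vc <- vc_from_par(opt$par[-seq_len(n_thr)], model)
  th <- opt$par[seq_len(n_thr)]
  thn <- if (thresholds == "shared") c("t_x", "t_y")
         else as.vector(t(outer(names(tables), c("t_x", "t_y"), paste,
                                sep = ".")))
  structure(list(
    model = model, thresholds_mode = thresholds,
    components = vc, derived = derived,
    thresholds = setNames(th, thn),
    loglik = -opt$value, k = length(opt$par),
    AIC = 2 * opt$value + 2 * length(opt$par),
    vcov_par = Vp, convergence = opt$convergence, restarts = tries,
    classes = names(tables)),
    class = "bivariate_fit")
}

#' @export
print.bivariate_fit <- function(x, ...) {
  cat(sprintf("bivariate %s liability fit (%s)%s\n", x$model,
              paste(x$classes, collapse = " + "),
              if (x$convergence != 0) " [NOT CONVERGED]" else ""))
  show <- c("a2_x", "a2_y", "coher_A", "rg")
  d <- x$derived[show, ]
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s = %.3f (95%% CI %.3f, %.3f)\n", show[i],
                d$estimate[i], d$lo[i], d$hi[i]))
  cat(sprintf("  loglik %.2f, AIC %.2f, k=%d\n", x$loglik, x$AIC, x$k))
  invisible(x)
}

#' Select the best-fitting model by AIC
#'
#' Returns the fit with the lowest AIC; exact ties break toward the model
#' with fewer free parameters.
#'
#' @param fits list of fits carrying `AIC` and `k` fields.
#' @return the selected fit.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stopf("need at least one fit")
  aic <- vapply(fits, function(f) f$AIC, 0)
  k <- vapply(fits, function(f) f$k, 0)
  fits[[order(aic, k)[1L]]]
}

#' Closed-form AE solution from tetrachoric correlations
#'
#' Pair-count-weighted least-squares solution of the linear AE system
#' relating observed tetrachoric correlations to variance components:
#' for each relative class `c`, within-trait cross-member correlation
#' `r_c = kA_c * a2`, cross-trait cross-member correlation
#' `x_c = kA_c * covA`, and within-individual phenotypic correlation
#' `phen = covA + covE`.  Weights are proportional to pair counts.
#' Negative implied components are clipped to the AE boundary and flagged.
#'
#' @param cors data.frame with one row per relative class and columns
#'   `class`, `r_within_x`, `r_within_y`, `r_cross`, `r_phen`.
#' @param weights pair counts, one per row of `cors`.
#' @return list with per-trait `a2`, `e2`, covariances `covA`, `covE`,
#'   `phen_cov`, coheritabilities `coher_A`, `coher_E`, correlations `rg`,
#'   `re`, and a `clipped` flag.
#' @export
solve_ae_from_correlations <- function(cors, weights) {
  if (nrow(cors) < 2L) stopf("both sister classes must be supplied")
  kA <- vapply(cors$class, function(l) relatedness_class(l)$kA, 0)
  w <- weights
  denom <- sum(w * kA^2)
  a2x <- sum(w * kA * cors$r_within_x) / denom
  a2y <- sum(w * kA * cors$r_within_y) / denom
  covA <- sum(w * kA * cors$r_cross) / denom
  phen <- sum(w * cors$r_phen) / sum(w)
  clipped <- FALSE
  clip01 <- function(x) {
    if (x < 0 || x > 1) clipped <<- TRUE
    min(max(x, 0), 1)
  }
  a2x <- clip01(a2x); a2y <- clip01(a2y)
  e2x <- 1 - a2x; e2y <- 1 - a2y
  covE <- phen - covA
  rg <- if (a2x * a2y > 0) covA / sqrt(a2x * a2y) else NA_real_
  re <- if (e2x * e2y > 0) covE / sqrt(e2x * e2y) else NA_real_
  if (!is.na(rg) && abs(rg) > 1) clipped <- TRUE
  list(a2 = c(a2x, a2y), e2 = c(e2x, e2y),
       covA = covA, covE = covE, phen_cov = phen,
       coher_A = covA / phen, coher_E = covE / phen,
       rg = rg, re = re, clipped = clipped)
}
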