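test_that("prevalence-threshold mapping inverts the normal CDF", {
  expect_equal(threshold_from_prevalence(.5), 0, tolerance = 1e-12)
  expect_equal(threshold_from_prevalence(.025), 1.95996, tolerance = 1e-4)
  expect_lt(threshold_from_prevalence(.9), 0)
  expect_equal(pnorm(threshold_from_prevalence(.0123)), 1 - .0123,
               tolerance = 1e-12)
  expect_error(threshold_from_prevalence(0), "strictly in")
})

test_that("tetrachoric MLE: independence, boundary, and grid-search oracle", {
  # cells proportional to products of margins -> r ~ 0
  ind <- matrix(c(720, 180, 80, 20), 2)   # margins .8/.2 and .9/.1
  est <- tetrachoric_mle(ind)
  expect_lt(abs(est$rho), 0.01)

  # diagonal table (no discordants) -> boundary flag
  diag_tab <- matrix(c(500, 0, 0, 50), 2)
  expect_true(tetrachoric_mle(diag_tab)$boundary)

  expect_error(tetrachoric_mle(matrix(c(10, 0, 5, 0), 2)), "zero margin")

  # brute-force grid search over r as the independent oracle
  library(mvtnorm)
  grid_oracle <- function(tab) {
    n <- sum(tab)
    t1 <- qnorm(1 - sum(tab[2, ]) / n)
    t2 <- qnorm(1 - sum(tab[, 2]) / n)
    rs <- seq(-0.999, 0.999, by = 1e-3)
    ll <- vapply(rs, function(r) {
      F00 <- as.numeric(pmvnorm(upper = c(t1, t2),
                                corr = matrix(c(1, r, r, 1), 2),
                                algorithm = TVPACK()))
      p <- pmax(c(F00, pnorm(t1) - F00, pnorm(t2) - F00,
                  1 - pnorm(t1) - pnorm(t2) + F00), 1e-300)
      tab[1, 1] * log(p[1]) + tab[1, 2] * log(p[2]) +
        tab[2, 1] * log(p[3]) + tab[2, 2] * log(p[4])
    }, 0)
    rs[which.max(ll)]
  }
  set.seed(31)
  for (i in 1:6) {
    tab <- matrix(rpois(4, lambda = c(200, 40, 40, 25)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(tetrachoric_mle(tab)$rho, grid_oracle(tab),
                 tolerance = 2e-3)
  }
})

test_that("pair model matrix implements the coefficient algebra", {
  vc <- list(a2 = c(1, 1), d2 = c(0, 0), c2 = c(0, 0), e2 = c(0, 0),
             covA = 1, covD = 0, covC = 0, covE = 0)
  R <- pair_model_matrix(vc, "full_sister")
  expect_equal(R[1, 3], 0.5)    # cross-sister same trait
  expect_equal(R[1, 4], 0.5)    # cross-sister cross trait
  expect_equal(R[1, 2], 1)      # within-individual cross trait

  vc2 <- list(a2 = c(.82, .4), d2 = c(0, 0), c2 = c(0, 0), e2 = c(.18, .6),
              covA = .08, covD = 0, covC = 0, covE = .1)
  expect_equal(pair_model_matrix(vc2, "full_sister")[1, 3], 0.41)
  expect_equal(pair_model_matrix(vc2, "maternal_half_sister")[1, 3], 0.205)

  # all-zero sharing coefficients -> block-diagonal matrix
  none <- structure(list(label = "unrelated", kA = 0, kD = 0, kC = 0),
                    class = "relatedness_class")
  R0 <- pair_model_matrix(vc2, none)
  expect_equal(R0[1:2, 3:4], matrix(0, 2, 2))
})

test_that("joint univariate AE fit recovers a simulated heritability", {
  arch <- architecture_spec(a2 = c(.8, .8), rA = 1, prevalence = c(.02, .02))
  tabs <- simulate_pair_tables(c(full_sister = 150000,
                                 maternal_half_sister = 30000),
                               arch, seed = 33)
  trips <- lapply(tabs, function(cl) {
    m <- apply(cl, c(1, 3), sum)
    c(m[2, 2], m[1, 1], m[1, 2] + m[2, 1])
  })
  fit <- fit_univariate(trips, model = "AE")
  expect_equal(unname(fit$estimates["a2"]), 0.8, tolerance = 0.08)
  expect_true(fit$ci["a2", "lo"] < 0.8 && fit$ci["a2", "hi"] > 0.8)
  expect_error(fit_univariate(trips[1]), ">= 2 relative classes")
})

test_that("AIC bookkeeping: richer models never lose likelihood; ties prefer parsimony", {
  arch <- architecture_spec(a2 = c(.6, .6), rA = 1, prevalence = c(.05, .05))
  tabs <- simulate_pair_tables(c(full_sister = 40000,
                                 maternal_half_sister = 15000),
                               arch, seed = 34)
  trips <- lapply(tabs, function(cl) {
    m <- apply(cl, c(1, 3), sum)
    c(m[2, 2], m[1, 1], m[1, 2] + m[2, 1])
  })
  ae <- fit_univariate(trips, model = "AE")
  ace <- fit_univariate(trips, model = "ACE")
  expect_gte(ace$loglik, ae$loglik - 1e-4)
  expect_equal(ae$AIC, -2 * ae$loglik + 2 * ae$k)

  # select_model: lowest AIC wins; exact ties break toward fewer parameters
  expect_identical(select_model(list(ae)), ae)
  f1 <- list(AIC = 10, k = 3); f2 <- list(AIC = 12, k = 2)
  expect_identical(select_model(list(f1, f2)), f1)
  g1 <- list(AIC = 10, k = 3); g2 <- list(AIC = 10, k = 2)
  expect_identical(select_model(list(g1, g2)), g2)
})

test_that("bivariate AE fit recovers a known architecture within its CIs", {
  arch <- test_arch()                      # a2 (.82, .45), rg .37
  tabs <- simulate_pair_tables(c(full_sister = 100000,
                                 maternal_half_sister = 20000),
                               arch, seed = 35)
  fit <- fit_bivariate(tabs, model = "AE", seed = 35)
  expect_equal(fit$convergence, 0)
  d <- fit$derived
  expect_lt(abs(d["a2_x", "estimate"] - .82), 3 * d["a2_x", "se"])
  expect_lt(abs(d["a2_y", "estimate"] - .45), 3 * d["a2_y", "se"])
  expect_lt(abs(d["rg", "estimate"] - .37), 3 * d["rg", "se"])
  # AE identities
  expect_equal(d["coher_A", "estimate"] + d["coher_E", "estimate"], 1,
               tolerance = 1e-8)
  expect_lte(abs(d["rg", "estimate"]), 1)
  expect_error(fit_bivariate(tabs[1]), ">= 2 relative classes")
})

test_that("correlation-based AE solution solves consistent inputs exactly", {
  cors <- data.frame(class = c("full_sister", "maternal_half_sister"),
                     r_within_x = c(.41, .205),
                     r_within_y = c(.41, .205),
                     r_cross = c(.04, .02),
                     r_phen = c(.19, .19))
  sol <- solve_ae_from_correlations(cors, weights = c(334433, 57036))
  expect_equal(sol$a2[1], .82, tolerance = 1e-12)
  expect_equal(sol$covA, .08, tolerance = 1e-12)
  expect_equal(sol$coher_A, .08 / .19, tolerance = 1e-12)
  expect_false(sol$clipped)
  # inconsistent inputs get clipped and flagged
  bad <- cors; bad$r_within_x <- c(2.2, 1.1)
  expect_true(solve_ae_from_correlations(bad, c(1, 1))$clipped)
  expect_error(solve_ae_from_correlations(cors[1, ], 1), "both sister")
})
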