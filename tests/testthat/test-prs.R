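make_ss <- function(n, seed = 1) {
  withr::with_seed(seed, {
    a1 <- sample(c("A", "C", "G", "T"), n, TRUE)
    a2 <- vapply(a1, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                 "")
    data.frame(snp = sprintf("v%03d", 1:n), chr = 1L, pos = 1000L * (1:n),
               a1 = a1, a2 = unname(a2), beta = rnorm(n),
               p = runif(n), freq = runif(n, .01, .99),
               info = runif(n, .5, 1), stringsAsFactors = FALSE)
  })
}

test_that("QC filter applies inclusive MAF/INFO bounds and ambiguity policy", {
  ss <- make_ss(6)
  ss$freq <- c(.04, .05, .50, .95, .30, .30)
  ss$info <- c(.9, .80, .79, .9, .9, .9)
  ss$a1 <- c("A", "A", "A", "A", "A", "C")
  ss$a2 <- c("C", "C", "C", "C", "T", "G")
  out <- qc_filter(ss)
  expect_equal(out$snp, c("v002", "v004"))   # .05/.80 inclusive; A/T, C/G dropped
  out2 <- qc_filter(ss, drop_ambiguous = FALSE)
  expect_true("v005" %in% out2$snp)
  expect_equal(nrow(qc_filter(ss[0, ])), 0L)
  ss$info <- NULL
  expect_warning(qc_filter(ss), "INFO")
  expect_error(qc_filter(ss["snp"]), "missing sumstats")
})

test_that("greedy clumping keeps the smallest-p variant per LD neighbourhood", {
  # three mutually correlated variants: only the most significant survives
  withr::with_seed(41, {
    base <- rbinom(400, 2, .4)
    G <- cbind(base,
               ifelse(runif(400) < .85, base, rbinom(400, 2, .4)),
               ifelse(runif(400) < .85, base, rbinom(400, 2, .4)))
  })
  ref <- list(geno = G,
              map = data.frame(id = c("s1", "s2", "s3"), chr = 1L,
                               pos = c(1e5, 2e5, 3e5)))
  ss <- data.frame(snp = c("s1", "s2", "s3"), chr = 1L,
                   pos = c(1e5, 2e5, 3e5),
                   a1 = "A", a2 = "C",
                   beta = 1, p = c(1e-8, 1e-4, 1e-2),
                   freq = .4, info = 1)
  expect_gt(min(cor(G)^2), 0.1)
  out <- ld_clump(ss, ref, r2_max = .1, window_kb = 1000)
  expect_equal(out$snp, "s1")

  # uncorrelated panel: everything survives
  withr::with_seed(42, G2 <- matrix(rbinom(400 * 3, 2, .3), 400))
  ref2 <- list(geno = G2, map = ref$map)
  expect_equal(nrow(ld_clump(ss, ref2, .1, 1000)), 3L)

  # random panels against the rule-checking oracle
  for (s in 1:60) {
    spec <- geno_panel_spec(n_variants = 10, block_length = 5, block_r = .6,
                            n_causal = 2, h2 = .3, n_discovery = 150,
                            n_target = 150)
    sim <- simulate_genotypes_and_sumstats(spec, seed = 500 + s)
    sst <- sim$sumstats
    kept <- ld_clump(sst, sim$target, r2_max = .1, window_kb = 30)
    expect_true(oracle_clump_valid(sst, kept$snp, sim$target, .1, 30),
                info = paste("panel", s))
  }
})

test_that("scoring handles weights, allele flips, missingness and linearity", {
  map <- data.frame(id = c("v1", "v2"), chr = 1L, pos = c(100L, 200L),
                    a1 = c("A", "G"), a2 = c("C", "T"))
  ss <- data.frame(snp = c("v1", "v2"), chr = 1L, pos = c(100L, 200L),
                   a1 = c("A", "G"), a2 = c("C", "T"),
                   beta = c(.5, -.2), p = c(.01, .20), freq = c(.3, .4),
                   info = 1)
  G <- rbind(c(2, 0), c(0, 1), c(1, 2))
  tgt <- list(geno = G, map = map)
  sc <- prs_score(ss, tgt, p_threshold = 1)
  expect_equal(sc$raw, as.vector(G %*% c(.5, -.2)))
  expect_equal(mean(sc$standardized), 0, tolerance = 1e-9)
  expect_equal(var(sc$standardized), 1, tolerance = 1e-9)
  expect_equal(prs_score(ss[1, ], list(geno = G[, 1, drop = FALSE] * 0,
                                       map = map[1, ]), 1)$raw,
               rep(0, 3))

  # relabeling a variant to the opposite allele orientation leaves scores
  # unchanged: dosage becomes 2 - dosage, alleles swap
  tgt_flip <- tgt
  tgt_flip$map$a1[1] <- "C"; tgt_flip$map$a2[1] <- "A"
  tgt_flip$geno[, 1] <- 2 - tgt_flip$geno[, 1]
  expect_equal(prs_score(ss, tgt_flip, 1)$raw, sc$raw)

  # missing dosages imputed to 2 * effect-allele frequency
  G2 <- G; G2[2, 1] <- NA
  sc2 <- prs_score(ss, list(geno = G2, map = map), 1)
  expect_equal(sc2$raw[2], .5 * 2 * .3 + (-.2) * 1)

  # irreconcilable alleles dropped with a message; zero variants errors
  ss_bad <- ss; ss_bad$a1[2] <- "A"; ss_bad$a2[2] <- "C"
  expect_message(prs_score(ss_bad, tgt, 1), "irreconcilable")
  expect_error(prs_score(ss, tgt, 1e-10), "zero variants")

  # score linearity over concatenated panels
  sc_a <- prs_score(ss[1, ], tgt, 1)$raw
  sc_b <- prs_score(ss[2, ], tgt, 1)$raw
  expect_equal(sc_a + sc_b, sc$raw)

  # threshold monotonicity of the variant count
  counts <- vapply(c(.05, .3, 1), function(pt)
    prs_score(ss, tgt, pt)$n_variants, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("scale scoring follows the instruments' conventions", {
  atac <- matrix(1, 2, 19,
                 dimnames = list(NULL, c(paste0("inatt", 1:9),
                                         paste0("hyp", 1:10))))
  expect_equal(scale_scores(atac, "atac_full"), c(19, 19))
  mixed <- atac; mixed[1, ] <- 0; mixed[1, 1:9] <- 0.5
  expect_equal(scale_scores(mixed, "atac_inattention")[1], 4.5)
  edi <- matrix(2, 3, 22,
                dimnames = list(NULL, c(paste0("dt", 1:7), paste0("bul", 1:7),
                                        paste0("bd", 1:8))))
  expect_equal(scale_scores(edi, "edi_full"), rep(2, 3))
  expect_equal(scale_scores(edi, "edi_dt"), rep(2, 3))
  bad <- edi; bad[1, 1] <- 7
  expect_error(scale_scores(bad, "edi_full"), "out-of-range")
  # missing policy
  miss <- edi; miss[1, 1] <- NA
  expect_true(is.na(scale_scores(miss, "edi_full")[1]))
  expect_equal(scale_scores(miss, "edi_full", missing = "available")[1], 2)
})

test_that("Cronbach's alpha matches its closed forms", {
  # two perfectly correlated items
  z <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(z, z)), 1, tolerance = 1e-12)
  # three items with exact pairwise correlation .5: a common factor plus
  # orthonormal mean-zero unique parts (column-centered QR basis)
  M <- scale(withr::with_seed(51, matrix(rnorm(9 * 5), 9)),
             center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))[, 1:4]
  X <- Q[, 2:4] + Q[, 1]
  expect_equal(cronbach_alpha(X), 0.75, tolerance = 1e-10)
  # independent items: alpha near zero
  Y <- withr::with_seed(52, matrix(rnorm(4000 * 5), ncol = 5))
  expect_lt(abs(cronbach_alpha(Y)), 0.1)
  # zero-variance item excluded with warning in the standardized variant
  expect_warning(cronbach_alpha(cbind(z, z, rep(1, 50))), "zero-variance")
  expect_error(cronbach_alpha(z), "at least two")
})

test_that("independence GEE equals OLS with cluster-robust errors", {
  withr::with_seed(61, {
    n <- 10000
    cl <- rep(seq_len(n / 2), each = 2)
    u <- rnorm(n / 2)[cl]                     # shared twin-pair effect
    prs <- rnorm(n)
    cov <- data.frame(sex = rbinom(n, 1, .5), by = sample(1992:2005, n, TRUE))
    y <- .03 * prs + .5 * u + rnorm(n, sd = sqrt(.77^2 - .25))
  })
  g <- gee_linear(y, prs, covariates = cov, clusters = cl)
  # point estimate equals OLS
  ols <- lm(y ~ prs + sex + by, data = cbind(cov, y = y, prs = prs))
  expect_equal(g$beta, unname(coef(ols)["prs"]), tolerance = 1e-12)
  # effect recovery at symptom-scale magnitudes
  expect_lt(abs(g$beta - .03), 3 * g$se)
  expect_gt(g$delta_r2, 0)
  expect_lt(g$delta_r2, 0.006)
  # null score: beta ~ 0, delta R2 ~ 0
  g0 <- gee_linear(y, withr::with_seed(62, rnorm(n)), covariates = cov,
                   clusters = cl)
  expect_lt(abs(g0$beta), 3 * g0$se)
  expect_lt(g0$delta_r2, 5e-4)
  # singleton clusters reduce to heteroskedasticity-robust OLS
  g1 <- gee_linear(y, prs, covariates = cov)
  hc <- sandwich::vcovHC(g1$full, type = "HC1")   # lm small-sample default
  expect_equal(g1$se, sqrt(hc["prs", "prs"]), tolerance = 1e-10)
  # collinear covariates are reported
  expect_warning(gee_linear(y, prs, covariates = cbind(cov, dup = cov$sex),
                            clusters = cl), "rank-deficient")
})
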