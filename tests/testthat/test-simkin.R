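test_that("pedigree structures define the intended relative classes", {
  ped <- simulate_pedigree(1, pattern = "two_full_sisters", seed = 1)
  off <- ped[ped$offspring, ]
  expect_equal(nrow(off), 2L)
  expect_true(all(off$sex == "F"))
  expect_equal(off$mid[1], off$mid[2])
  expect_equal(off$pid[1], off$pid[2])

  ped <- simulate_pedigree(1, pattern = "maternal_half_sisters", seed = 2)
  off <- ped[ped$offspring, ]
  expect_equal(off$mid[1], off$mid[2])
  expect_false(off$pid[1] == off$pid[2])

  expect_error(simulate_pedigree(0), "positive integer")
})

test_that("pair enumeration equals the brute-force all-pairs oracle", {
  ped <- simulate_pedigree(120, pattern = "mixed", seed = 1)
  oracle <- oracle_pair_counts(ped)
  for (cl in names(oracle)) {
    got <- nrow(enumerate_pairs(ped, cl, sex_filter = NULL))
    expect_equal(got, unname(oracle[cl]), info = cl)
  }
  # classes are mutually exclusive per pair
  cp <- liabkin:::classify_pairs(ped)
  expect_false(anyDuplicated(paste(cp$i, cp$j)) > 0)
})

test_that("identical seeds give byte-identical outputs", {
  p1 <- simulate_pedigree(50, seed = 7)
  p2 <- simulate_pedigree(50, seed = 7)
  expect_identical(p1, p2)
  arch <- test_arch()
  expect_identical(simulate_liabilities(p1, arch, seed = 8),
                   simulate_liabilities(p2, arch, seed = 8))
  spec <- geno_panel_spec(n_variants = 60, n_causal = 5,
                          n_discovery = 200, n_target = 100)
  expect_identical(simulate_genotypes_and_sumstats(spec, seed = 9),
                   simulate_genotypes_and_sumstats(spec, seed = 9))
})

test_that("cross-sister liability covariance matches the class coefficients", {
  # a2 = .82, full sisters: expected cross-sister correlation .5 * .82 = .41
  arch <- architecture_spec(a2 = c(.82, .82), rA = 1, prevalence = c(.02, .02),
                            traits = c("x", "y"))
  ped <- simulate_pedigree(50000, pattern = "two_full_sisters", seed = 7)
  L <- simulate_liabilities(ped, arch, seed = 7)
  off <- which(ped$offspring)
  s1 <- L[off[seq(1, length(off), 2)], 1]
  s2 <- L[off[seq(2, length(off), 2)], 1]
  mc_se <- (1 - 0.41^2) / sqrt(50000)
  expect_equal(cor(s1, s2), 0.41, tolerance = 3 * mc_se)
  expect_equal(var(s1), 1, tolerance = 0.02)

  # pure unique environment: no cross-sister correlation
  arch0 <- architecture_spec(e2 = c(1, 1), prevalence = c(.05, .05))
  L0 <- simulate_liabilities(ped, arch0, seed = 8)
  z1 <- L0[off[seq(1, length(off), 2)], 1]
  z2 <- L0[off[seq(2, length(off), 2)], 1]
  expect_lt(abs(cor(z1, z2)), 3 / sqrt(50000) * 1.5)
})

test_that("pair-covariance recovery holds across classes and architectures", {
  grid <- list(
    list(arch = test_arch(a2 = c(.6, .3), rA = .5, rE = .1),
         cl = "maternal_half_sister"),
    list(arch = architecture_spec(a2 = c(.4, .4), c2 = c(.3, .2), rA = .3,
                                  rC = .5, prevalence = c(.05, .05)),
         cl = "full_sister"))
  for (g in grid) {
    cls <- relatedness_class(g$cl)
    R <- pair_model_matrix(g$arch, cls)
    n <- 40000
    ped <- simulate_pedigree(n, pattern = if (g$cl == "full_sister")
      "two_full_sisters" else "maternal_half_sisters", seed = 21)
    L <- simulate_liabilities(ped, g$arch, seed = 22)
    off <- which(ped$offspring)
    M <- cbind(L[off[seq(1, length(off), 2)], ],
               L[off[seq(2, length(off), 2)], ])
    emp <- cor(M)
    expect_true(max(abs(emp - R)) < 3 * 1.2 / sqrt(n))
  }
})

test_that("thresholding reproduces the target prevalence", {
  expect_identical(threshold_diagnose(c(-1, 1), 0.5), c(0L, 1L))
  expect_true(all(threshold_diagnose(rnorm(100), 1 - 1e-12) == 1L))
  expect_error(threshold_diagnose(rnorm(5), 1.2), "strictly in")
  x <- withr::with_seed(3, rnorm(1e6))
  frac <- mean(threshold_diagnose(x, 0.019))
  se <- sqrt(0.019 * 0.981 / 1e6)
  expect_lt(abs(frac - 0.019), 4 * se)
})

test_that("simulated genotypes realize the nominal LD and GWAS behaviour", {
  # null panel: p-values uniform
  spec0 <- geno_panel_spec(n_variants = 400, block_length = 8, block_r = .5,
                           n_causal = 0, h2 = 0, n_discovery = 800,
                           n_target = 50)
  sim0 <- simulate_genotypes_and_sumstats(spec0, seed = 31)
  ks <- suppressWarnings(stats::ks.test(sim0$sumstats$p, "punif"))
  expect_gt(ks$p.value, 0.001)

  # single causal variant with a large discovery sample: top association at
  # the causal variant or an LD proxy in its block
  spec1 <- geno_panel_spec(n_variants = 200, block_length = 10, block_r = .8,
                           n_causal = 1, h2 = 0.25, n_discovery = 4000,
                           n_target = 50)
  sim1 <- simulate_genotypes_and_sumstats(spec1, seed = 32)
  top <- which.min(sim1$sumstats$p)
  cb <- (sim1$causal$index - 1) %/% 10
  expect_equal((top - 1) %/% 10, cb)

  # nominal adjacent correlation realized: block_r .9 -> r^2 ~ .81
  spec2 <- geno_panel_spec(n_variants = 300, block_length = 10, block_r = .9,
                           n_causal = 0, h2 = 0, n_discovery = 100,
                           n_target = 4000)
  sim2 <- simulate_genotypes_and_sumstats(spec2, seed = 33)
  G <- sim2$target$geno
  j <- setdiff(seq_len(299), seq(10, 300, 10))   # within-block neighbours
  r2 <- vapply(j, function(k) cor(G[, k], G[, k + 1])^2, 0)
  expect_equal(mean(r2), 0.81, tolerance = 0.02)
})

test_that("symptom scales hit their floors, alpha target and genetic signal", {
  g <- withr::with_seed(41, rnorm(5000))
  items <- simulate_symptom_scales(g, "atac", effect = 0.3,
                                   target_alpha = 0.9, seed = 141)
  expect_true(all(items %in% c(0, 0.5, 1)))
  expect_equal(cronbach_alpha(items), 0.9, tolerance = 0.03)
  sc <- scale_scores(items, "atac_full")
  expect_gt(cor(sc, g), 0.15)

  # scale floors
  allmin <- matrix(0, 3, 19,
                   dimnames = list(NULL, colnames(items)))
  expect_equal(scale_scores(allmin, "atac_full"), rep(0, 3))
  edi <- simulate_symptom_scales(g[1:100], "edi", seed = 42)
  allnever <- matrix(1, 3, 22, dimnames = list(NULL, colnames(edi)))
  expect_equal(scale_scores(allnever, "edi_full"), rep(1, 3))

  # near-deterministic monotone link when the factor is pure genetic value
  items2 <- simulate_symptom_scales(g, "edi", effect = 1,
                                    target_alpha = 0.95, seed = 43)
  expect_gt(cor(scale_scores(items2, "edi_full"), g, method = "spearman"),
            0.8)
})
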