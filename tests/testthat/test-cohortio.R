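test_that("pedigree and sumstats TSVs round-trip losslessly", {
  ped <- simulate_pedigree(20, pattern = "mixed", seed = 5)
  arch <- test_arch()
  liab <- simulate_liabilities(ped, arch, seed = 6)
  ped$dx_x <- threshold_diagnose(liab[, 1], .05)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(as.data.frame(ped), as.data.frame(back))

  spec <- geno_panel_spec(n_variants = 40, n_causal = 4, n_discovery = 200,
                          n_target = 30)
  sim <- simulate_genotypes_and_sumstats(spec, seed = 7)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(sim$sumstats, f2)
  back2 <- read_sumstats(f2)
  expect_equal(sim$sumstats, back2, tolerance = 1e-12)
})

test_that("VCF writer/reader round-trips dosages and variant metadata", {
  spec <- geno_panel_spec(n_variants = 25, n_causal = 2, n_discovery = 100,
                          n_target = 12)
  sim <- simulate_genotypes_and_sumstats(spec, seed = 8)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$target, f)
  back <- read_vcf(f)
  expect_equal(back$geno, sim$target$geno, tolerance = 1e-6)
  expect_equal(back$map$id, sim$target$map$id)
  expect_equal(back$map$a1, sim$target$map$a1)
  expect_equal(as.integer(back$map$pos), sim$target$map$pos)
})

test_that("pair enumeration honors one-per-family and twin exclusion", {
  ped <- simulate_pedigree(1, pattern = "two_full_sisters", n_children = 3,
                           seed = 9)
  expect_equal(nrow(enumerate_pairs(ped, "full_sister")), 3L)  # 3 choose 2
  one <- enumerate_pairs(ped, "full_sister", one_per_family = TRUE, seed = 1)
  expect_equal(nrow(one), 1L)
  # selection is uniform under the seed, and reproducible
  expect_identical(one,
                   enumerate_pairs(ped, "full_sister", one_per_family = TRUE,
                                   seed = 1))
  tw <- simulate_pedigree(5, pattern = "twin_pairs", seed = 10)
  expect_equal(nrow(enumerate_pairs(tw, "full_sibling", sex_filter = NULL,
                                    exclude_twins = TRUE)), 0L)
})

test_that("pair tabulation is exhaustive, symmetric and margin-consistent", {
  ped <- simulate_pedigree(2, pattern = "two_full_sisters", seed = 11)
  off <- ped$iid[ped$offspring]
  ped$dx_a <- ifelse(ped$iid %in% off, 1L, NA_integer_)
  ped$dx_b <- ped$dx_a
  prs <- enumerate_pairs(ped, "full_sister")
  tab1 <- tabulate_pairs(prs, ped, "dx_a")
  expect_equal(tab1$both_affected, 2)
  expect_equal(tab1$both_unaffected, 0)
  expect_equal(tab1$discordant, 0)

  tab2 <- tabulate_pairs(prs, ped, c("dx_a", "dx_b"))
  expect_equal(sum(tab2$cells), 2)
  expect_equal(tab2$cells[2, 2, 2, 2], 2)

  # orientation swap leaves the one-trait table invariant
  swapped <- prs
  swapped$i <- prs$j; swapped$j <- prs$i
  attr(swapped, "class_label") <- attr(prs, "class_label")
  tab1s <- tabulate_pairs(swapped, ped, "dx_a")
  expect_equal(tab1$table, tab1s$table)

  # independent random traits: cells close to products of margins
  ped2 <- simulate_pedigree(4000, pattern = "two_full_sisters", seed = 12)
  withr::with_seed(13, {
    ped2$dx_a <- rbinom(nrow(ped2), 1, 0.3)
    ped2$dx_b <- rbinom(nrow(ped2), 1, 0.2)
  })
  prs2 <- enumerate_pairs(ped2, "full_sister")
  t16 <- tabulate_pairs(prs2, ped2, c("dx_a", "dx_b"))
  n <- t16$n_pairs
  # unordered pairs with one member (a=1, b=0), the other (a=0, b=0):
  # multinomial expectation 2 * (.3*.8) * (.7*.8) per pair
  p_cell <- 2 * (.3 * .8) * (.7 * .8)
  got <- t16$cells[1, 1, 2, 1] + t16$cells[2, 1, 1, 1]
  expect_lt(abs(got - n * p_cell), 5 * sqrt(n * p_cell * (1 - p_cell)))

  # missing values: dropped and counted
  ped2$dx_a[match(prs2$i[1], ped2$iid)] <- NA
  t16b <- tabulate_pairs(prs2, ped2, c("dx_a", "dx_b"))
  expect_equal(t16b$n_dropped, 1)
  expect_error(tabulate_pairs(prs2, ped2, "nope"), "not in table")
})

test_that("published-summary reconstruction splits discordants evenly", {
  pt <- pair_table_2x2(787, 322529, 11117)
  expect_equal(pt$table[1, 2], 11117 / 2)
  expect_equal(pt$table[2, 1], 11117 / 2)
  expect_equal(sum(pt$table), 334433)
  expect_error(pair_table_2x2(-1, 2, 3), "non-negative")
})

test_that("prevalence summaries use rounded percentages and flag empty strata", {
  ped <- simulate_pedigree(300, pattern = "two_full_sisters", seed = 14)
  withr::with_seed(15, {
    ped$dx_s <- rbinom(nrow(ped), 1, 0.2)
    ped$dx_t <- rbinom(nrow(ped), 1, 0.1)
  })
  tab <- prevalence_summary(ped, stratify_by = "dx_s", traits = "dx_t")
  row <- tab[tab$sex == "all" & tab$stratum == 1, ]
  expect_equal(row$pct, round_half_up(100 * row$count / row$n, 1))
  # all-female pedigree: male strata are empty and flagged
  male <- tab[tab$sex == "M", ]
  expect_true(all(male$flagged))
  expect_true(all(is.na(male$pct)))
})

test_that("half-up rounding matches registry table formatting", {
  expect_equal(round_half_up(2.65, 1), 2.7)
  expect_equal(round_half_up(2.649, 1), 2.6)
  expect_equal(round_half_up(3.05, 1), 3.1)
})
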