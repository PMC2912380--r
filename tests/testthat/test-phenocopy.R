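test_that("level 0 is a strict no-op for every injector", {
  pool <- toy_pool(seed = 1)
  tab <- toy_epi_table(pool, seed = 2)
  ds <- build_cc_pool(pool, tab, pool_spec(2, 50, 50, seed = 3))
  res <- sample_population_controls(pool, tab, 100, seed = 4)
  expect_identical(pm1_case_control(ds, res, 0, seed = 5), ds)
  expect_identical(pm2_case_control(ds, phenocopy_spec("PM2", 0, list(a = tab)), pool), ds)
  ped <- build_pedigree_pool(pool, tab, n_replicates = 1, seed = 6,
                             families_per_config = 3)
  expect_identical(pm1_pedigree(ped, 0, seed = 7), ped)
})

test_that("phenocopy counts are exact with round-half-away rounding", {
  pool <- toy_pool(seed = 8)
  tab <- toy_epi_table(pool, seed = 9)
  ds <- build_cc_pool(pool, tab, pool_spec(1, 10, 10, seed = 10))
  res <- sample_population_controls(pool, tab, 50, seed = 11)
  # 0.45 * 10 = 4.5 -> 5 phenocopies, half away from zero
  out <- pm1_case_control(ds, res, 0.45, seed = 12)
  expect_equal(sum(out$phenocopy_flag == "PM1"), 5)
  expect_equal(sum(out$status), 10)          # case count unchanged
  expect_true(all(out$phenocopy_flag[out$status == 0L] == "none"))
  # larger dataset, level grid
  ds2 <- build_cc_pool(pool, tab, pool_spec(4, 50, 50, seed = 13))
  res2 <- sample_population_controls(pool, tab, 200, seed = 14)
  for (lev in c(0.05, 0.10, 0.20, 0.30, 0.45)) {
    out2 <- pm1_case_control(ds2, res2, lev, seed = 15)
    expect_equal(sum(out2$phenocopy_flag == "PM1"), round(lev * 200))
  }
  expect_error(pm1_case_control(ds2, res2, 1.2, seed = 1), "level")
  expect_error(pm1_case_control(ds2, sample_population_controls(pool, tab, 3, seed = 1),
                                0.45, seed = 1), "reservoir")
})

test_that("PM1 injection follows the dilution law at the causal locus", {
  pool <- toy_pool(seed = 16)
  model <- anchor_prevalence(logistic_disease_model(0, c("RL0-10" = 0.9)), pool, 0.10)
  ds <- build_cc_pool(pool, model, pool_spec(10, 200, 200, seed = 17))
  res <- sample_population_controls(pool, model, 1500, seed = 18)
  g <- ds$genotypes$genotypes[, "RL0-10"]
  p_case <- mean(g[ds$status == 1L]) / 2
  p_pop <- pool_allele_freq(pool)[["RL0-10"]]
  for (lev in c(0.20, 0.45)) {
    out <- pm1_case_control(ds, res, lev, seed = 19)
    expected <- (1 - lev) * p_case + lev * p_pop
    got <- mean(out$genotypes$genotypes[out$status == 1L, "RL0-10"]) / 2
    se <- sqrt(expected * (1 - expected) / (2 * 2000))
    expect_lt(abs(got - expected), 3 * se)
  }
  # flagged rows carry the control genotype distribution at the causal locus
  out <- pm1_case_control(ds, res, 0.45, seed = 19)
  flagged <- out$genotypes$genotypes[out$phenocopy_flag == "PM1", "RL0-10"]
  se_f <- sqrt(p_pop * (1 - p_pop) / (2 * length(flagged)))
  expect_lt(abs(mean(flagged) / 2 - p_pop), 4 * se_f)
  # nesting under a common seed: lower levels substitute a subset of cases
  f20 <- which(pm1_case_control(ds, res, 0.20, seed = 19)$phenocopy_flag == "PM1")
  f45 <- which(out$phenocopy_flag == "PM1")
  expect_true(all(f20 %in% f45))
})

test_that("PM1 pedigree swaps preserve every family's design counts", {
  pool <- toy_pool(seed = 20)
  tab <- toy_epi_table(pool, seed = 21)
  ped <- build_pedigree_pool(pool, tab, n_replicates = 4, seed = 22)
  n_aff <- sum(ped$sibs$status == 1L & ped$sibs$constrained)
  for (lev in c(0.10, 0.30, 0.45)) {
    out <- pm1_pedigree(ped, lev, seed = 23)
    expect_equal(sum(out$sibs$flag == "PM1"), round(lev * n_aff))
    # affected counts among constrained sibs unchanged in every family
    before <- tapply(ped$sibs$status[ped$sibs$constrained],
                     ped$sibs$fam[ped$sibs$constrained], sum)
    after <- tapply(out$sibs$status[out$sibs$constrained],
                    out$sibs$fam[out$sibs$constrained], sum)
    expect_equal(before, after)
    # every flagged sib is now affected and was unaffected in the base data
    fl <- out$sibs$flag == "PM1"
    expect_true(all(out$sibs$status[fl] == 1L))
    expect_true(all(ped$sibs$status[fl] == 0L))
  }
  # nesting across levels
  f10 <- which(pm1_pedigree(ped, 0.10, seed = 23)$sibs$flag == "PM1")
  f30 <- which(pm1_pedigree(ped, 0.30, seed = 23)$sibs$flag == "PM1")
  expect_true(all(f10 %in% f30))
})

test_that("PM2 phenocopies come from their own determinants, unlike PM1", {
  pool <- toy_pool(n_markers = 60, pinned = c("RL0-10", "RL0-50"), seed = 24)
  main <- anchor_prevalence(logistic_disease_model(0, c("RL0-10" = 0.9)), pool, 0.10)
  alt <- anchor_prevalence(logistic_disease_model(0, c("RL0-50" = 0.9)), pool, 0.10)
  ds <- build_cc_pool(pool, main, pool_spec(8, 200, 200, seed = 25))
  spec <- phenocopy_spec("PM2", 0.45, list(altB = alt), seed = 26)
  out <- pm2_case_control(ds, spec, pool)
  expect_equal(sum(out$phenocopy_flag == "PM2:altB"), round(0.45 * 1600))
  expect_equal(sum(out$status), sum(ds$status))
  p_pop_B <- pool_allele_freq(pool)[["RL0-50"]]
  flagged <- out$phenocopy_flag != "none"
  # flagged rows are enriched at the alternative-model locus...
  expect_gt(mean(out$genotypes$genotypes[flagged, "RL0-50"]) / 2, p_pop_B + 0.03)
  # ...while PM1 phenocopies are enriched nowhere
  res <- sample_population_controls(pool, main, 800, seed = 27)
  out1 <- pm1_case_control(ds, res, 0.45, seed = 28)
  fl1 <- out1$phenocopy_flag == "PM1"
  se <- sqrt(p_pop_B * (1 - p_pop_B) / (2 * sum(fl1)))
  expect_lt(abs(mean(out1$genotypes$genotypes[fl1, "RL0-50"]) / 2 - p_pop_B), 4 * se)
  # dilution: causal-locus chi-square decreases monotonically along the ladder
  chis <- sapply(c(0, 0.2, 0.45), function(lev) {
    d <- pm2_case_control(ds, phenocopy_spec("PM2", lev, list(altB = alt), seed = 26), pool)
    sc <- single_point_scan(d)
    sc$chi2_allelic[match("RL0-10", sc$marker)]
  })
  expect_true(all(diff(chis) < 0))
  # substituted-case set nests across levels under a common seed
  f20 <- which(pm2_case_control(ds, phenocopy_spec("PM2", 0.2, list(altB = alt), seed = 26),
                                pool)$phenocopy_flag != "none")
  f45 <- which(flagged)
  expect_true(all(f20 %in% f45))
  # empty alt-model list is a parameter error
  expect_error(phenocopy_spec("PM2", 0.2, list()), "alternative")
})
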