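test_that("logistic model maps beta to the per-allele odds ratio exactly", {
  m <- logistic_disease_model(-2, c("RL0-855" = 0.8))
  odds <- function(g) {
    p <- logistic_penetrance(m, c("RL0-855" = g))
    p / (1 - p)
  }
  # per-allele OR = exp(0.8), to 9 decimals
  expect_equal(odds(1) / odds(0), 2.225540928, tolerance = 1e-9)
  # closed-form odds check between g=2 and g=1, machine precision
  expect_equal(odds(2) / odds(1), exp(0.8), tolerance = 1e-12)
  # null model: penetrance is constant at plogis(alpha)
  m0 <- logistic_disease_model(-1.2, c("RL0-855" = 0))
  for (g in 0:2)
    expect_equal(logistic_penetrance(m0, c("RL0-855" = g)), stats::plogis(-1.2))
  # missing marker is a model error
  expect_error(logistic_penetrance(m, c("RL0-1" = 1)), "lack")
})

test_that("interaction terms enter as dosage products", {
  m <- logistic_disease_model(
    -1, c(A = 0.2, B = 0.1),
    interactions = list(list(loci = c("A", "B", "C"), gamma = 0.3)))
  g <- c(A = 2, B = 1, C = 2)
  eta <- -1 + 0.2 * 2 + 0.1 * 1 + 0.3 * (2 * 1 * 2)
  expect_equal(logistic_penetrance(m, g), stats::plogis(eta), tolerance = 1e-14)
})

test_that("table marginals and prevalence agree with direct enumeration", {
  # flat table: every marginal equals the cell value, prevalence too
  ft <- flat_table(0.07)
  tm <- table_marginals(ft)
  expect_equal(as.numeric(tm$marginals), rep(0.07, 9))
  expect_equal(tm$prevalence, 0.07)
  expect_equal(ft$marginal_dev, 0)
  expect_true(is.na(table_achieved_or(ft)))  # single-class table: OR undefined

  # random table: prevalence equals an independently coded HWE summation
  set.seed(42)
  cells <- runif(27)
  tab <- penetrance_table(c("A", "B", "C"), cells, maf = c(0.3, 0.4, 0.25))
  direct <- 0
  hw <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)
  for (g1 in 0:2) for (g2 in 0:2) for (g3 in 0:2) {
    w <- hw(0.3)[g1 + 1] * hw(0.4)[g2 + 1] * hw(0.25)[g3 + 1]
    direct <- direct + w * cells[1 + g1 + 3 * g2 + 9 * g3]
  }
  expect_equal(table_marginals(tab)$prevalence, direct, tolerance = 1e-14)
})

test_that("a two-locus XOR-style table at maf 0.5 has exactly equal marginals", {
  # high penetrance iff exactly one locus is heterozygous
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  cells <- ifelse(xor(g$g1 == 1, g$g2 == 1), 0.8, 0.1)
  tab <- penetrance_table(c("A", "B"), cells, maf = 0.5)
  tm <- table_marginals(tab)
  expect_equal(max(abs(tm$marginals - tm$prevalence)), 0, tolerance = 1e-15)
})

test_that("the GA finds a zero-marginal table at the target odds ratio", {
  cfg <- epistatic_search_config(target_or = 4, maf = 0.3, seed = 19)
  tab <- generate_epistatic_table(cfg)
  expect_lte(tab$marginal_dev, cfg$marginal_tolerance)
  expect_lt(abs(log(tab$achieved_or / 4)), log(1.1))
  expect_lt(abs(tab$prevalence - 0.10), 0.02)
  expect_true(all(tab$cells >= 0 & tab$cells <= 1))
  tr <- attr(tab, "trace")
  expect_equal(nrow(tr), cfg$generations)
  expect_true(!is.unsorted(tr$fitness))  # elitism: best fitness non-decreasing
  # determinism under the seed
  tab2 <- generate_epistatic_table(cfg)
  expect_equal(tab$cells, tab2$cells)
})

test_that("a hopeless GA budget signals a convergence error carrying its best table", {
  cfg <- epistatic_search_config(target_or = 4, maf = 0.3, generations = 2,
                                 population_size = 8, marginal_tolerance = 1e-12,
                                 seed = 3)
  err <- tryCatch(generate_epistatic_table(cfg), condition = function(c) c)
  expect_s3_class(err, "phenobench_convergence_error")
  expect_s3_class(err$table, "penetrance_table")
})

test_that("penetrance tables round-trip through their text serialization", {
  tab <- toy_epi_table(toy_pool(seed = 4), seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_penetrance_table(tab, path)
  back <- read_penetrance_table(path)
  expect_equal(back$cells, tab$cells, tolerance = 1e-12)
  expect_equal(back$loci, tab$loci)
  expect_equal(back$maf, tab$maf, tolerance = 1e-9)
  expect_equal(back$achieved_or, tab$achieved_or, tolerance = 1e-9)
})

test_that("assign_status reproduces the model penetrance", {
  pool <- toy_pool(seed = 5)
  gm <- sample_genotypes(pool, 100000, seed = 6)
  # penetrance identically 1: everyone affected
  expect_true(all(assign_status(gm, flat_table(1, loci = c("RL0-10", "RL0-25", "RL0-40"))) == 1L))
  # flat 0.1: binomial oracle
  st <- assign_status(gm, flat_table(0.1, loci = c("RL0-10", "RL0-25", "RL0-40")), seed = 2)
  se <- sqrt(0.1 * 0.9 / 100000)
  expect_lt(abs(mean(st) - 0.1), 3 * se)
  # determinism
  expect_identical(assign_status(gm, flat_table(0.1, loci = c("RL0-10", "RL0-25", "RL0-40")), seed = 3),
                   assign_status(gm, flat_table(0.1, loci = c("RL0-10", "RL0-25", "RL0-40")), seed = 3))
})

test_that("a positive main effect enriches the minor allele among the affected", {
  pool <- toy_pool(seed = 8)
  model <- anchor_prevalence(
    logistic_disease_model(0, c("RL0-10" = 0.8)), pool, 0.10)
  gm <- sample_genotypes(pool, 20000, seed = 9)
  st <- assign_status(gm, model, seed = 10)
  g <- gm$genotypes[, "RL0-10"]
  tt <- t.test(g[st == 1L], g[st == 0L], alternative = "greater")
  expect_lt(tt$p.value, 0.001)
  # anchored prevalence is honoured
  expect_lt(abs(mean(st) - 0.10), 0.01)
})
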