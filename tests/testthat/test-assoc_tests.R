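test_that("allelic chi-square matches hand-computed contingency values", {
  # identical case/control genotype distributions: chi2 = 0, p = 1
  ds0 <- cc_from_counts(c(10, 20, 10), c(10, 20, 10))
  sc0 <- single_point_scan(ds0)
  expect_equal(sc0$chi2_allelic, 0)
  expect_equal(sc0$p_allelic, 1)
  # case alleles (60 minor, 40 major) vs control (40, 60): all expected
  # cells are 50, chi2 = 4 * 100/50 = 8
  ds1 <- cc_from_counts(c(0, 40, 10), c(10, 40, 0))
  sc1 <- single_point_scan(ds1)
  expect_equal(sc1$chi2_allelic, 8, tolerance = 1e-12)
  expect_equal(sc1$or_allelic, (60 * 60) / (40 * 40), tolerance = 1e-12)
  # monomorphic marker: flagged, p = 1, OR undefined
  dsm <- cc_from_counts(c(30, 0, 0), c(30, 0, 0))
  scm <- single_point_scan(dsm)
  expect_true(scm$monomorphic)
  expect_equal(scm$p_allelic, 1)
  expect_true(is.na(scm$or_allelic))
})

test_that("scan statistics match brute-force oracles on 1000 random tables", {
  set.seed(77)
  worst_allelic <- worst_trend <- worst_hwe <- 0
  for (i in 1:1000) {
    r <- stats::rmultinom(1, sample(20:60, 1), runif(3, 0.05, 1))[, 1]
    s <- stats::rmultinom(1, sample(20:60, 1), runif(3, 0.05, 1))[, 1]
    ds <- cc_from_counts(r, s)
    sc <- single_point_scan(ds)
    a <- r[2] + 2 * r[3]; b <- 2 * sum(r) - a
    cc <- s[2] + 2 * s[3]; d <- 2 * sum(s) - cc
    if ((a + cc) > 0 && (b + d) > 0) {
      oracle <- suppressWarnings(
        stats::chisq.test(rbind(c(a, b), c(cc, d)), correct = FALSE))$statistic
      worst_allelic <- max(worst_allelic, abs(sc$chi2_allelic - oracle))
    }
    tr <- tryCatch(suppressWarnings(
      stats::prop.trend.test(r, r + s, score = 0:2))$statistic,
      error = function(e) NA)
    if (!is.na(tr)) worst_trend <- max(worst_trend, abs(sc$chi2_trend - tr))
    # HWE oracle: direct expected-count computation in controls
    hw <- hwe_scan(ds)
    n <- sum(s); ph <- (s[2] + 2 * s[3]) / (2 * n)
    if (ph > 0 && ph < 1) {
      e <- n * c((1 - ph)^2, 2 * ph * (1 - ph), ph^2)
      worst_hwe <- max(worst_hwe, abs(hw$chi2 - sum((s - e)^2 / e)))
    }
  }
  expect_lt(worst_allelic, 1e-10)
  expect_lt(worst_trend, 1e-10)
  expect_lt(worst_hwe, 1e-10)
})

test_that("HWE screen matches closed-form expectations", {
  # perfect HWE at p = 0.5
  ds <- cc_from_counts(c(1, 1, 1), c(25, 50, 25))
  hw <- hwe_scan(ds)
  expect_equal(hw$chi2, 0, tolerance = 1e-12)
  expect_equal(hw$p, 1)
  # all-homozygote controls at p = 0.5: chi2 = n = 100
  ds2 <- cc_from_counts(c(1, 1, 1), c(50, 0, 50))
  hw2 <- hwe_scan(ds2)
  expect_equal(hw2$chi2, 100, tolerance = 1e-12)
  expect_true(hw2$flag)
})

test_that("TDT counts transmissions correctly and matches McNemar", {
  # closed form: b = 15, c = 5 -> chi2 = 100/20 = 5
  expect_equal((15 - 5)^2 / (15 + 5),
               unname(stats::mcnemar.test(matrix(c(0, 15, 5, 0), 2),
                                          correct = FALSE)$statistic))
  pool <- toy_pool(n_markers = 45, seed = 30)
  tab <- toy_epi_table(pool, seed = 31)
  ped <- build_pedigree_pool(pool, tab, n_replicates = 2, seed = 32,
                             families_per_config = 10)
  res <- tdt_scan(ped)
  # independent recount: plain R loop over affected sibs and parents
  fa1 <- phenobench:::rows_to_haplotypes(pool, ped$FA1)
  fa2 <- phenobench:::rows_to_haplotypes(pool, ped$FA2)
  mo1 <- phenobench:::rows_to_haplotypes(pool, ped$MO1)
  mo2 <- phenobench:::rows_to_haplotypes(pool, ped$MO2)
  M <- ncol(fa1)
  b <- c_ <- numeric(M)
  s <- ped$sibs
  for (i in which(s$status == 1L)) {
    f <- s$fam[i]
    for (m in seq_len(M)) {
      if (fa1[f, m] != fa2[f, m]) {
        tr <- if (s$tf[i] == 1L) fa1[f, m] else fa2[f, m]
        if (tr == 1L) b[m] <- b[m] + 1 else c_[m] <- c_[m] + 1
      }
      if (mo1[f, m] != mo2[f, m]) {
        tr <- if (s$tm[i] == 1L) mo1[f, m] else mo2[f, m]
        if (tr == 1L) b[m] <- b[m] + 1 else c_[m] <- c_[m] + 1
      }
    }
  }
  expect_equal(res$b, b)
  expect_equal(res$c, c_)
  expect_equal(res$chi2, ifelse(b + c_ > 0, (b - c_)^2 / (b + c_), 0),
               tolerance = 1e-12)
  expect_true(all(res$chi2[res$b == res$c] == 0))
})

test_that("null scans produce uniform p values", {
  # no disease locus: affection assigned at random
  mm <- build_marker_map(200, block_size_range = c(1, 1), seed = 40)
  pool <- build_haplotype_pool(mm, ld_decay = 0, pool_size = 2000, seed = 41)
  gm <- sample_genotypes(pool, 2000, seed = 42)
  null_model <- logistic_disease_model(stats::qlogis(0.5), c("RL0-0" = 0))
  st <- assign_status(gm, null_model, seed = 43)
  ds <- phenobench:::new_cc_dataset(gm, st)
  sc <- single_point_scan(ds)
  expect_gt(stats::ks.test(sc$p_allelic, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(sc$p_trend, "punif")$p.value, 0.01)
})

test_that("the interaction regression is calibrated and recovers planted effects", {
  pool <- toy_pool(n_markers = 45, seed = 50)
  loci <- c("RL0-1", "RL0-5", "RL0-9")
  gm <- sample_genotypes(pool, 800, seed = 51)
  # null calibration: shuffled status -> roughly uniform p over replicates
  ps <- sapply(1:40, function(r) {
    st <- local({ set.seed(r); sample(rep(0:1, 400)) })
    ds <- phenobench:::new_cc_dataset(gm, st)
    logistic_interaction_test(ds, loci)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # planted three-way effect: coefficient sign recovered in >95% of replicates
  planted <- logistic_disease_model(
    -1.2, interactions = list(list(loci = loci, gamma = 0.5)))
  signs <- sapply(1:30, function(r) {
    g <- sample_genotypes(pool, 1500, seed = 100 + r)
    st <- assign_status(g, planted, seed = 200 + r)
    ds <- phenobench:::new_cc_dataset(g, st)
    sign(logistic_interaction_test(ds, loci)$coefficient)
  })
  expect_gte(mean(signs == 1), 0.95)
})
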