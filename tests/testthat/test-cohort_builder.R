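test_that("case-control sampling meets its quotas exactly", {
  pool <- toy_pool(seed = 1)
  tab <- toy_epi_table(pool, seed = 2)
  ds <- sample_case_control(pool, tab, 200, 200, seed = 3)
  expect_equal(length(ds$status), 400)
  expect_equal(sum(ds$status == 1L), 200)
  expect_equal(sum(ds$status == 0L), 200)
  expect_true(all(ds$phenocopy_flag == "none"))
  # controls only
  ds0 <- sample_case_control(pool, tab, 0, 25, seed = 4)
  expect_equal(sum(ds0$status), 0)
  expect_equal(length(ds0$status), 25)
  # degenerate model: quota unreachable within the draw cap
  expect_error(
    sample_case_control(pool, flat_table(0, loci = c("RL0-10", "RL0-25", "RL0-40")),
                        10, 0, seed = 5, max_draws = 5000),
    "rejection sampling")
})

test_that("cases are enriched in the high-risk genotype class as enumeration predicts", {
  pool <- toy_pool(seed = 6)
  tab <- toy_epi_table(pool, seed = 7)
  ds <- sample_case_control(pool, tab, 2000, 2000, seed = 8)
  # expected class occupancy by exact enumeration over the 27 cells
  w <- phenobench:::table_cell_weights(tab$maf)
  hi_cells <- tab$cells > tab$prevalence
  p_pop_hi <- sum(w[hi_cells])
  prev <- tab$prevalence
  p_case_hi <- sum(w[hi_cells] * tab$cells[hi_cells]) / prev
  p_ctrl_hi <- sum(w[hi_cells] * (1 - tab$cells[hi_cells])) / (1 - prev)
  idx <- phenobench:::mdr_cell_index(ds$genotypes$genotypes[, tab$loci], 1:3)
  in_hi <- hi_cells[idx]
  se_case <- sqrt(p_case_hi * (1 - p_case_hi) / 2000)
  se_ctrl <- sqrt(p_ctrl_hi * (1 - p_ctrl_hi) / 2000)
  expect_lt(abs(mean(in_hi[ds$status == 1L]) - p_case_hi), 3 * se_case)
  expect_lt(abs(mean(in_hi[ds$status == 0L]) - p_ctrl_hi), 3 * se_ctrl)
  expect_gt(mean(in_hi[ds$status == 1L]), mean(in_hi[ds$status == 0L]))
})

test_that("pooled case-control datasets concatenate replicates faithfully", {
  pool <- toy_pool(seed = 9)
  tab <- toy_epi_table(pool, seed = 10)
  ds <- build_cc_pool(pool, tab, pool_spec(3, 50, 50, seed = 11))
  expect_equal(length(ds$status), 300)
  expect_equal(as.integer(table(ds$replicate_id)), rep(100L, 3))
  expect_equal(sum(ds$status == 1L), 150)
  # pooled minor-allele count equals the sum over replicates (exact identity)
  per_rep <- sapply(1:3, function(r) colSums(ds$genotypes$genotypes[ds$replicate_id == r, ]))
  expect_equal(colSums(ds$genotypes$genotypes), rowSums(per_rep))
  # degenerate pool spec
  tiny <- build_cc_pool(pool, tab, pool_spec(1, 1, 1, seed = 12))
  expect_equal(length(tiny$status), 2)
})

test_that("ascertained families match their configuration exactly", {
  pool <- toy_pool(seed = 13)
  tab <- toy_epi_table(pool, seed = 14)
  fam <- sample_family(pool, tab, 1, 2, 0, seed = 15)
  expect_equal(ped_n_individuals(fam), 5)
  expect_equal(sum(fam$sibs$status == 1L), 1)
  parents_only <- sample_family(pool, tab, 0, 0, 0, seed = 16)
  expect_equal(ped_n_individuals(parents_only), 2)

  ped <- build_pedigree_pool(pool, tab, n_replicates = 1, seed = 17)
  expect_equal(ped_n_individuals(ped), 500)  # 25 * (5 + 6 + 9)
  expect_equal(as.integer(table(ped$families$config_label)), rep(25L, 3))
  # 100% of families show the required affected pattern among constrained sibs
  want <- c("1a2u" = 1L, "3a1u" = 3L, "2a2u3r" = 2L)
  s <- ped$sibs
  aff_con <- tapply(s$status[s$constrained], s$fam[s$constrained], sum)
  aff_con <- aff_con[as.character(seq_len(nrow(ped$families)))]
  expect_equal(as.integer(aff_con), unname(want[ped$families$config_label]))
})

test_that("pedigree genotypes are Mendelian-consistent at every marker", {
  pool <- toy_pool(n_markers = 45, seed = 18)
  tab <- toy_epi_table(pool, seed = 19)
  ped <- build_pedigree_pool(pool, tab, n_replicates = 1, seed = 20,
                             families_per_config = 4)
  g <- ped_genotypes(ped)
  s <- ped$sibs
  # child dosage equals transmitted father hap + transmitted mother hap
  fa1 <- phenobench:::rows_to_haplotypes(pool, ped$FA1)
  fa2 <- phenobench:::rows_to_haplotypes(pool, ped$FA2)
  mo1 <- phenobench:::rows_to_haplotypes(pool, ped$MO1)
  mo2 <- phenobench:::rows_to_haplotypes(pool, ped$MO2)
  for (i in seq_len(nrow(s))) {
    tf <- if (s$tf[i] == 1L) fa1[s$fam[i], ] else fa2[s$fam[i], ]
    tm <- if (s$tm[i] == 1L) mo1[s$fam[i], ] else mo2[s$fam[i], ]
    expect_identical(unname(g$sibs[i, ]), unname(tf + tm))
  }
  # and the paternal/maternal contribution is always one of the parent's alleles
  expect_true(all(g$sibs <= g$father[s$fam, ] + g$mother[s$fam, ]))
  both_zero <- g$father[s$fam, ] == 0 & g$mother[s$fam, ] == 0
  expect_true(all(g$sibs[both_zero] == 0))
})
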