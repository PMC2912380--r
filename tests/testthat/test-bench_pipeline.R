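test_that("PED/MAP round-trips preserve case-control data exactly", {
  pool <- toy_pool(n_markers = 5, pinned = "RL0-2", seed = 80)
  tab <- flat_table(0.3, loci = c("RL0-2", "RL0-3", "RL0-4"))
  ds <- sample_case_control(pool, tab, 5, 5, seed = 81)
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "toy.ped"); map <- file.path(dir, "toy.map")
  write_ped_map(ds, ped, map)
  back <- read_ped_map(ped, map)
  expect_s3_class(back, "cc_dataset")
  expect_equal(unname(back$genotypes$genotypes), unname(ds$genotypes$genotypes))
  expect_equal(back$status, ds$status)   # phenotype 2 = affected honoured
  # allele order within a genotype is unordered: swap the first genotype's
  # alleles in the text and re-read
  lines <- readLines(ped)
  f <- strsplit(lines[1], " ")[[1]]
  f[7:8] <- f[8:7]
  writeLines(c(paste(f, collapse = " "), lines[-1]), ped)
  back2 <- read_ped_map(ped, map)
  expect_equal(back2$genotypes$genotypes, back$genotypes$genotypes)
  # malformed line raises a parse error
  writeLines(c(lines, "fam bad"), ped)
  expect_error(read_ped_map(ped, map), "malformed|columns")
})

test_that("PED/MAP round-trips preserve pedigree structure and genotypes", {
  pool <- toy_pool(n_markers = 8, pinned = "RL0-2", seed = 82)
  tab <- flat_table(0.3, loci = c("RL0-2", "RL0-3", "RL0-4"))
  ped_ds <- build_pedigree_pool(pool, tab, n_replicates = 1, seed = 83,
                                families_per_config = 2)
  dir <- withr::local_tempdir()
  pedf <- file.path(dir, "fam.ped"); mapf <- file.path(dir, "fam.map")
  write_ped_map(ped_ds, pedf, mapf)
  back <- read_ped_map(pedf, mapf)
  expect_s3_class(back, "ped_table")
  g <- ped_genotypes(ped_ds)
  s <- ped_ds$sibs
  ids <- paste0(ped_ds$families$family_id[s$fam], "_s", s$sib)
  rows <- match(ids, back$info$id)
  expect_false(anyNA(rows))
  expect_equal(unname(back$genotypes[rows, ]), unname(g$sibs))
  expect_equal(back$info$pheno[rows], ifelse(s$status == 1L, 2L, 1L))
  # parent links intact
  expect_true(all(back$info$father[rows] ==
                    paste0(ped_ds$families$family_id[s$fam], "_f")))
})

test_that("false-positive summaries match their binomial expectation", {
  # threshold 1 counts every non-causal marker
  mm <- build_marker_map(120, block_size_range = c(1, 1), seed = 90)
  pool <- build_haplotype_pool(mm, ld_decay = 0, pool_size = 1500, seed = 91)
  gm <- sample_genotypes(pool, 1500, seed = 92)
  st <- assign_status(gm, logistic_disease_model(stats::qlogis(0.5),
                                                c("RL0-0" = 0)), seed = 93)
  ds <- phenobench:::new_cc_dataset(gm, st)
  sc <- single_point_scan(ds)
  expect_equal(summarize_false_positives(sc, 1, causal = "RL0-0"), 119)
  # null simulation: count ~ Binomial(M, alpha)
  alpha <- 0.05
  cnt <- summarize_false_positives(sc, alpha, causal = "RL0-0")
  se <- sqrt(119 * alpha * (1 - alpha))
  expect_lt(abs(cnt - 119 * alpha), 4 * se)
  expect_error(summarize_false_positives(sc, 0), "threshold")
})

test_that("flat key-value configs round-trip", {
  path <- withr::local_tempfile(fileext = ".cfg")
  write_flat_config(list(n_markers = 401, levels = c(0, 0.05, 0.45),
                         label = "EPI"), path)
  back <- read_flat_config(path)
  expect_equal(back$n_markers, 401)
  expect_equal(back$levels, c(0, 0.05, 0.45))
  expect_equal(back$label, "EPI")
})

test_that("a toy benchmark grid runs end to end with dilution and full bookkeeping", {
  dir <- withr::local_tempdir()
  cfg <- benchmark_config(models = "EPI", levels = c(0, 0.45),
                          cc_replicates = 4, ped_replicates = 2,
                          epi_markers = 401, pool_size = 200,
                          seed = 7, output_dir = dir)
  out <- run_benchmark(cfg)
  expect_length(out$failures, 0)
  tab <- out$table
  # grid arithmetic: cc (2 methods x 2 levels) + pedigree (2 levels)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$design == "cc"), 4)
  # dilution at toy scale: the 0%-level MDR odds ratio is not below the 45% one
  for (m in c("PM1", "PM2")) {
    sub <- tab[tab$design == "cc" & tab$method == m, ]
    expect_gte(sub$mdr_testing_or[sub$level == 0],
               sub$mdr_testing_or[sub$level == 0.45])
  }
  # manifest and per-cell artifacts exist; the run is resumable
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  expect_true(file.exists(file.path(dir, "degradation.tsv")))
  first_rows <- list.files(dir, pattern = "\\.row\\.tsv$")
  expect_equal(length(first_rows), 6)
  out2 <- run_benchmark(cfg)   # resumes from the row files
  expect_equal(out2$table$neglog10p, tab$neglog10p, tolerance = 1e-9)
})
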