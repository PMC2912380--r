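#' Benchmark configuration for the full phenocopy-degradation grid
#'
#' The default grid is the full study design: two disease models (ME, EPI),
#' two phenocopy mechanisms (PM1, PM2 -- PM2 for case-control only), six
#' phenocopy levels (0/5/10/20/30/45%), case-control pools of
#' 50 x (200 + 200) and pedigree pools of 50 replicates of the three family
#' configurations. The `toy` preset shrinks the chromosomes and replicate
#' counts for fast runs.
#'
#' @param models subset of `c("ME", "EPI")`
#' @param designs subset of `c("cc", "pedigree")`
#' @param methods subset of `c("PM1", "PM2")`
#' @param levels phenocopy levels, ascending, starting at 0
#' @param cc_replicates,cases_per_replicate,controls_per_replicate pooled
#'   case-control design
#' @param ped_replicates,families_per_config pooled pedigree design
#' @param me_markers,epi_markers chromosome sizes
#' @param pool_size,ld_decay haplotype-pool parameters
#' @param fp_alpha per-marker significance threshold for false-positive
#'   counting; `NULL` means Bonferroni 0.05 / n_markers
#' @param mdr_forced run forced-triple MDR on the EPI case-control arm
#' @param seed master seed
#' @param output_dir directory for per-cell result files and the manifest;
#'   `NULL` keeps everything in memory
#' @param toy logical: use a reduced preset (smaller chromosomes, 2
#'   replicates) suitable for smoke runs
#' @return a `benchmark_config`
#' @export
benchmark_config <- function(models = c("ME", "EPI"),
                             designs = c("cc", "pedigree"),
                             methods = c("PM1", "PM2"),
                             levels = c(0, 0.05, 0.10, 0.20, 0.30, 0.45),
                             cc_replicates = 50L, cases_per_replicate = 200L,
                             controls_per_replicate = 200L,
                             ped_replicates = 50L, families_per_config = 25L,
                             me_markers = 1362L, epi_markers = 401L,
                             pool_size = 600L, ld_decay = 0.7,
                             fp_alpha = NULL, mdr_forced = TRUE,
                             seed = 1L, output_dir = NULL, toy = FALSE) {
  if (is.unsorted(levels) || levels[1L] != 0)
    stop("levels must be ascending and start at 0")
  if (toy) {
    cc_replicates <- 2L; ped_replicates <- 2L
    pool_size <- 200L
  }
  cfg <- list(models = match.arg(models, c("ME", "EPI"), several.ok = TRUE),
              designs = match.arg(designs, c("cc", "pedigree"), several.ok = TRUE),
              methods = match.arg(methods, c("PM1", "PM2"), several.ok = TRUE),
              levels = levels,
              cc_replicates = as.integer(cc_replicates),
              cases_per_replicate = as.integer(cases_per_replicate),
              controls_per_replicate = as.integer(controls_per_replicate),
              ped_replicates = as.integer(ped_replicates),
              families_per_config = as.integer(families_per_config),
              me_markers = as.integer(me_markers),
              epi_markers = as.integer(epi_markers),
              pool_size = as.integer(pool_size), ld_decay = ld_decay,
              fp_alpha = fp_alpha, mdr_forced = isTRUE(mdr_forced),
              seed = as.integer(seed), output_dir = output_dir, toy = toy)
  class(cfg) <- "benchmark_config"
  cfg
}

#' Count falsely significant markers in a scan
#'
#' @param results an `assoc_result` or `tdt_result` data.frame
#' @param threshold per-marker p-value threshold in (0, 1]
#' @param causal marker ids to exclude from counting (the modelled loci)
#' @param p_column which p value to use (default the first of `p_allelic`/`p`)
#' @return integer count of non-causal markers with p below the threshold
#' @export
summarize_false_positives <- function(results, threshold, causal = character(0),
                                      p_column = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (is.null(p_column))
    p_column <- if ("p_allelic" %in% names(results)) "p_allelic" else "p"
  keep <- !(results$marker %in% causal)
  sum(results[[p_column]][keep] <= threshold)
}

# rank of a marker by ascending p (1 = most significant)
marker_rank <- function(results, marker, p_column) {
  r <- rank(results[[p_column]], ties.method = "min")
  r[match(marker, results$marker)]
}

#' Run the phenocopy-degradation benchmark grid
#'
#' Executes simulate -> disease model -> pool -> phenocopy injection ->
#' analysis for every grid cell (model x design x method x level) and
#' collects one degradation row per cell: the causal marker's headline
#' statistic (-log10 p of the most significant causal locus; for the EPI
#' case-control arm also the forced-triple MDR testing metrics and the
#' interaction-regression p), the causal rank, and the false-positive count
#' at the chosen threshold. Per-cell scan tables and a manifest of resolved
#' parameters are written when `output_dir` is set; existing cell files are
#' not recomputed (resumable). Per-cell failures are recorded and the
#' remaining cells proceed.
#'
#' @param config a [benchmark_config()]
#' @return list with `table` (degradation data.frame), `failures`
#'   (per-cell error messages), and `studies` (the assembled study objects)
#' @export
run_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  studies <- list()
  rows <- list()
  failures <- list()
  max_level <- max(config$levels)

  for (model_name in config$models) {
    study <- if (model_name == "ME") {
      me_study(n_markers = config$me_markers, pool_size = config$pool_size,
               ld_decay = config$ld_decay, seed = child_seed(config$seed, "ME"))
    } else {
      epi_study(n_markers = config$epi_markers, pool_size = config$pool_size,
                ld_decay = config$ld_decay, seed = child_seed(config$seed, "EPI"))
    }
    studies[[model_name]] <- study
    fp_alpha <- if (is.null(config$fp_alpha)) 0.05 / nrow(study$markers) else config$fp_alpha

    if ("cc" %in% config$designs) {
      base_cc <- build_cc_pool(study$pool, study$model, pool_spec(
        config$cc_replicates, config$cases_per_replicate,
        config$controls_per_replicate,
        seed = child_seed(config$seed, paste0("cc-", model_name))))
      n_cases <- sum(base_cc$status == 1L)
      reservoir <- if ("PM1" %in% config$methods)
        sample_population_controls(study$pool, study$model,
                                   ceiling(max_level * n_cases) + 8L,
                                   seed = child_seed(config$seed, paste0("res-", model_name)))
      for (method in config$methods) {
        for (level in config$levels) {
          cell <- sprintf("%s_cc_%s_%02d", model_name, method, round(100 * level))
          res <- run_cell(cell, out_dir, failures, function() {
            ds <- if (method == "PM1") {
              pm1_case_control(base_cc, reservoir, level,
                               seed = child_seed(config$seed, paste0("pm1-", model_name)))
            } else {
              pm2_case_control(base_cc, phenocopy_spec(
                "PM2", level, study$alt_models,
                seed = child_seed(config$seed, paste0("pm2-", model_name))), study$pool)
            }
            analyze_cc_cell(ds, study, config, fp_alpha, model_name, method, level)
          })
          failures <- res$failures
          if (!is.null(res$row)) rows[[length(rows) + 1L]] <- res$row
        }
      }
    }

    if ("pedigree" %in% config$designs && "PM1" %in% config$methods) {
      base_ped <- build_pedigree_pool(study$pool, study$model,
                                      n_replicates = config$ped_replicates,
                                      seed = child_seed(config$seed, paste0("ped-", model_name)),
                                      families_per_config = config$families_per_config)
      for (level in config$levels) {
        cell <- sprintf("%s_pedigree_PM1_%02d", model_name, round(100 * level))
        res <- run_cell(cell, out_dir, failures, function() {
          ds <- pm1_pedigree(base_ped, level,
                             seed = child_seed(config$seed, paste0("pm1ped-", model_name)))
          analyze_ped_cell(ds, study, config, fp_alpha, model_name, level)
        })
        failures <- res$failures
        if (!is.null(res$row)) rows[[length(rows) + 1L]] <- res$row
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  if (!is.null(out_dir)) {
    utils::write.table(table, file.path(out_dir, "degradation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_manifest(file.path(out_dir, "manifest.txt"), config, failures)
  }
  list(table = table, failures = failures, studies = studies)
}

# Execute one grid cell with failure capture and per-cell resumability.
run_cell <- function(cell, out_dir, failures, fn) {
  row_file <- if (!is.null(out_dir)) file.path(out_dir, paste0(cell, ".row.tsv"))
  if (!is.null(out_dir) && file.exists(row_file)) {
    row <- utils::read.table(row_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    return(list(row = row, failures = failures))
  }
  row <- tryCatch(fn(), error = function(e) {
    failures[[cell]] <<- conditionMessage(e)
    NULL
  })
  if (!is.null(row) && !is.null(out_dir))
    utils::write.table(row, row_file, sep = "\t", row.names = FALSE, quote = FALSE)
  list(row = row, failures = failures)
}

analyze_cc_cell <- function(ds, study, config, fp_alpha, model_name, method, level) {
  scan <- single_point_scan(ds)
  hwe <- hwe_scan(ds, alpha = fp_alpha)
  causal <- study$causal
  best <- causal[which.min(scan$p_allelic[match(causal, scan$marker)])]
  row <- data.frame(
    model = model_name, design = "cc", method = method, level = level,
    analysis = "single_point",
    causal_marker = best,
    neglog10p = scan$neglog10p[match(best, scan$marker)],
    causal_rank = marker_rank(scan, best, "p_allelic"),
    false_positives = summarize_false_positives(scan, fp_alpha, study$all_causal),
    hwe_flagged = sum(hwe$flag[!(hwe$marker %in% study$all_causal)]),
    interaction_p = NA_real_, mdr_testing_or = NA_real_,
    mdr_testing_accuracy = NA_real_, stringsAsFactors = FALSE)
  if (model_name == "EPI") {
    it <- logistic_interaction_test(ds, study$causal)
    row$interaction_p <- it$p_value
    if (config$mdr_forced) {
      mdr <- mdr_evaluate(ds, study$causal,
                          mdr_config(seed = child_seed(config$seed, "mdr")))
      row$mdr_testing_or <- mdr$odds_ratio
      row$mdr_testing_accuracy <- mdr$testing_accuracy
    }
  }
  if (!is.null(config$output_dir)) {
    utils::write.table(
      scan, file.path(config$output_dir,
                      sprintf("%s_cc_%s_%02d_scan.tsv", model_name, method,
                              round(100 * level))),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  row
}

analyze_ped_cell <- function(ds, study, config, fp_alpha, model_name, level) {
  scan <- tdt_scan(ds)
  causal <- study$causal
  best <- causal[which.min(scan$p[match(causal, scan$marker)])]
  row <- data.frame(
    model = model_name, design = "pedigree", method = "PM1", level = level,
    analysis = "tdt",
    causal_marker = best,
    neglog10p = scan$neglog10p[match(best, scan$marker)],
    causal_rank = marker_rank(scan, best, "p"),
    false_positives = summarize_false_positives(scan, fp_alpha, study$all_causal),
    hwe_flagged = NA_integer_,
    interaction_p = NA_real_, mdr_testing_or = NA_real_,
    mdr_testing_accuracy = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(config$output_dir)) {
    utils::write.table(
      scan, file.path(config$output_dir,
                      sprintf("%s_pedigree_PM1_%02d_tdt.tsv", model_name,
                              round(100 * level))),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  row
}

# ---- flat key-value config / manifest -----------------------------------

#' Read / write a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric where possible, comma-separated values as vectors.
#'
#' @param path file path
#' @return named list of values
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[[2L]], "\\s*,\\s*")[[1L]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  stats::setNames(vals, vapply(kv, `[[`, "", 1L))
}

#' @param values named list to write
#' @rdname read_flat_config
#' @export
write_flat_config <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    paste0(k, " = ", paste(format(values[[k]], digits = 15), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

write_manifest <- function(path, config, failures) {
  vals <- config[!vapply(config, is.null, TRUE)]
  vals <- vals[vapply(vals, function(v) is.atomic(v) && length(v) >= 1L, TRUE)]
  vals$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  vals$package_version <- as.character(utils::packageVersion("phenobench"))
  vals$r_version <- as.character(getRversion())
  if (length(failures))
    vals$failed_cells <- paste(names(failures), collapse = ",")
  write_flat_config(vals, path)
}
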