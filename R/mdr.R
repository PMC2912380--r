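#' Multifactor dimensionality reduction configuration
#'
#' @param cv_folds number of stratified cross-validation folds (default 10)
#' @param ratio_threshold case:control ratio at or above which a genotype
#'   cell is labelled high-risk; `NULL` (default) uses the dataset-wide
#'   case:control ratio
#' @param search_budget number of random attribute combinations evaluated by
#'   [mdr_random_search()] (default 5000)
#' @param min_way,max_way combination sizes searched (default 2 to 4)
#' @param seed integer seed (fold assignment and search order)
#' @return an `mdr_config`
#' @export
mdr_config <- function(cv_folds = 10L, ratio_threshold = NULL,
                       search_budget = 5000L, min_way = 2L, max_way = 4L,
                       seed = 1L) {
  stopifnot(cv_folds >= 2, min_way >= 1, min_way <= max_way, search_budget >= 1)
  cfg <- list(cv_folds = as.integer(cv_folds), ratio_threshold = ratio_threshold,
              search_budget = as.integer(search_budget),
              min_way = as.integer(min_way), max_way = as.integer(max_way),
              seed = as.integer(seed))
  class(cfg) <- "mdr_config"
  cfg
}

# Multilocus cell index (1-based, first attribute fastest) for a dosage
# matrix restricted to the attribute columns.
mdr_cell_index <- function(G, attributes) {
  idx <- rep(1L, nrow(G))
  mult <- 1L
  for (a in attributes) {
    idx <- idx + as.integer(G[, a]) * mult
    mult <- mult * 3L
  }
  idx
}

#' Label multilocus genotype cells as high or low risk
#'
#' A cell is high-risk iff its case:control count ratio is at least
#' `ratio_threshold`; cells with controls but no cases are low-risk, cells
#' with cases but no controls are high-risk, and cells with neither are
#' `"empty"`. Ties (ratio exactly at the threshold) go high-risk.
#'
#' @param G dosage matrix (training split) with marker-id column names
#' @param status 0/1 affection vector aligned with `G`
#' @param attributes marker ids of the combination
#' @param ratio_threshold case:control ratio threshold
#' @return character vector over the `3^k` cells: `"high"`, `"low"` or
#'   `"empty"` (cell order: first attribute fastest)
#' @export
label_cells <- function(G, status, attributes, ratio_threshold = 1) {
  k <- length(attributes)
  idx <- mdr_cell_index(G[, attributes, drop = FALSE],
                        seq_len(k))
  nc <- 3^k
  cases <- tabulate(idx[status == 1L], nbins = nc)
  ctrls <- tabulate(idx[status == 0L], nbins = nc)
  lab <- rep("empty", nc)
  seen <- cases + ctrls > 0L
  hi <- seen & (cases >= ratio_threshold * ctrls)
  lab[seen] <- ifelse(hi[seen], "high", "low")
  lab
}

#' Evaluate one attribute combination by cross-validated MDR
#'
#' Stratified `cv_folds`-fold cross-validation: within each fold, genotype
#' cells are labelled high/low risk on the training part and test
#' individuals are classified (high-risk cell -> predicted case; test
#' individuals falling in a training-empty cell -> predicted low-risk).
#' Predictions are pooled over folds into a single 2x2 table, from which
#' balanced testing accuracy, sensitivity, specificity and the odds ratio
#' with a 95% Woolf (log-method) confidence interval are computed.
#'
#' @param ds a `cc_dataset`
#' @param attributes marker ids of the combination
#' @param config an [mdr_config()]
#' @return an `mdr_result`: attributes, full-data `cell_labels`, pooled 2x2
#'   counts, `testing_accuracy` (balanced), `sensitivity`, `specificity`,
#'   `odds_ratio` with `or_ci`, `or_corrected` flag (Haldane-Anscombe 0.5
#'   applied to a zero cell), `training_accuracy`, `cv_consistency`
#' @export
mdr_evaluate <- function(ds, attributes, config = mdr_config()) {
  stopifnot(inherits(ds, "cc_dataset"))
  G <- ds$genotypes$genotypes
  missing <- setdiff(attributes, colnames(G))
  if (length(missing)) stop("unknown attribute(s): ", paste(missing, collapse = ", "))
  y <- ds$status
  ncase <- sum(y == 1L); nctrl <- sum(y == 0L)
  if (ncase < config$cv_folds || nctrl < config$cv_folds)
    stop("need at least cv_folds cases and controls")
  thr <- if (is.null(config$ratio_threshold)) ncase / nctrl else config$ratio_threshold
  k <- length(attributes)
  idx <- mdr_cell_index(G[, attributes, drop = FALSE], seq_len(k))
  nc <- 3^k
  fold <- integer(length(y))
  local_rng(child_seed(config$seed, paste(c("mdr-folds", attributes), collapse = "-")), {
    fold[y == 1L] <- sample(rep_len(seq_len(config$cv_folds), ncase))
    fold[y == 0L] <- sample(rep_len(seq_len(config$cv_folds), nctrl))
  })
  full_labels <- label_cells(G, y, attributes, thr)
  tp <- fp <- tn <- fn <- 0L
  train_acc <- numeric(config$cv_folds)
  consistency <- numeric(config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- fold != f
    cases_tr <- tabulate(idx[tr & y == 1L], nbins = nc)
    ctrls_tr <- tabulate(idx[tr & y == 0L], nbins = nc)
    seen <- cases_tr + ctrls_tr > 0L
    hi <- seen & (cases_tr >= thr * ctrls_tr)   # empty cells classify low
    # training balanced accuracy for this fold
    sens_tr <- sum(cases_tr[hi]) / sum(cases_tr)
    spec_tr <- sum(ctrls_tr[!hi]) / sum(ctrls_tr)
    train_acc[f] <- (sens_tr + spec_tr) / 2
    lab_tr <- rep("empty", nc); lab_tr[seen] <- ifelse(hi[seen], "high", "low")
    nonempty <- seen & full_labels != "empty"
    consistency[f] <- if (any(nonempty))
      mean(lab_tr[nonempty] == full_labels[nonempty]) else NA_real_
    te <- which(!tr)
    pred <- hi[idx[te]]
    tp <- tp + sum(pred & y[te] == 1L)
    fn <- fn + sum(!pred & y[te] == 1L)
    fp <- fp + sum(pred & y[te] == 0L)
    tn <- tn + sum(!pred & y[te] == 0L)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  corrected <- any(c(tp, fp, tn, fn) == 0L)
  cc <- if (corrected) 0.5 else 0
  or <- ((tp + cc) * (tn + cc)) / ((fp + cc) * (fn + cc))
  se_log <- sqrt(1 / (tp + cc) + 1 / (fp + cc) + 1 / (tn + cc) + 1 / (fn + cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  res <- list(attributes = attributes,
              cell_labels = full_labels,
              counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
              testing_accuracy = (sens + spec) / 2,
              sensitivity = sens, specificity = spec,
              odds_ratio = or, or_ci = ci, or_corrected = corrected,
              training_accuracy = mean(train_acc),
              cv_consistency = mean(consistency, na.rm = TRUE),
              ratio_threshold = thr, cv_folds = config$cv_folds)
  class(res) <- "mdr_result"
  res
}

#' @export
print.mdr_result <- function(x, ...) {
  cat(sprintf("MDR %d-way [%s]\n", length(x$attributes),
              paste(x$attributes, collapse = ", ")))
  cat(sprintf("  testing accuracy %.4f (sens %.4f, spec %.4f)\n",
              x$testing_accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  testing OR %.4f (95%% CI %.4f-%.4f)%s\n",
              x$odds_ratio, x$or_ci[1], x$or_ci[2],
              if (x$or_corrected) " [0.5 corrected]" else ""))
  invisible(x)
}

#' Random non-exhaustive MDR model search
#'
#' Samples `search_budget` attribute combinations uniformly without
#' replacement from all combinations of sizes `min_way` to `max_way`,
#' evaluates each by [mdr_evaluate()], and ranks by testing accuracy. Falls
#' back to exhaustive enumeration when the budget covers the whole space.
#'
#' @param ds a `cc_dataset`
#' @param config an [mdr_config()]
#' @return list with `results` (ranked list of `mdr_result`) and `summary`
#'   (ranked data.frame: attributes, way, testing accuracy, OR)
#' @export
mdr_random_search <- function(ds, config = mdr_config()) {
  stopifnot(inherits(ds, "cc_dataset"))
  markers <- colnames(ds$genotypes$genotypes)
  M <- length(markers)
  ways <- seq.int(config$min_way, min(config$max_way, M))
  totals <- choose(M, ways)
  total <- sum(totals)
  combos <- local_rng(child_seed(config$seed, "mdr-search"), {
    if (config$search_budget >= total) {
      unlist(lapply(ways, function(w)
        utils::combn(markers, w, simplify = FALSE)), recursive = FALSE)
    } else {
      seen <- new.env(hash = TRUE)
      out <- vector("list", config$search_budget)
      got <- 0L
      while (got < config$search_budget) {
        w <- sample(ways, 1L, prob = totals)
        cmb <- sort(sample(markers, w))
        key <- paste(cmb, collapse = "|")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- cmb
        }
      }
      out
    }
  })
  results <- lapply(combos, function(cmb) mdr_evaluate(ds, cmb, config))
  acc <- vapply(results, `[[`, numeric(1), "testing_accuracy")
  ord <- order(acc, decreasing = TRUE)
  results <- results[ord]
  summary <- data.frame(
    rank = seq_along(results),
    attributes = vapply(results, function(r) paste(r$attributes, collapse = ","), ""),
    way = vapply(results, function(r) length(r$attributes), integer(1)),
    testing_accuracy = vapply(results, `[[`, numeric(1), "testing_accuracy"),
    odds_ratio = vapply(results, `[[`, numeric(1), "odds_ratio"),
    stringsAsFactors = FALSE)
  list(results = results, summary = summary)
}
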