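#' Construct a multi-locus penetrance table
#'
#' A penetrance table maps every multilocus genotype of `k` biallelic loci
#' (dosage-coded 0/1/2 each, `3^k` cells) to a probability of being affected.
#' Cell order: the first locus varies fastest, i.e. cell index
#' `1 + g1 + 3*g2 + 9*g3 + ...`.
#'
#' @param loci character vector of marker ids (length k)
#' @param cells numeric vector of `3^k` penetrances in `[0, 1]`
#' @param maf assumed minor allele frequency per locus (recycled to k); used
#'   for the Hardy-Weinberg weighting of marginals, prevalence and the
#'   achieved odds ratio
#' @return a `penetrance_table` with precomputed `prevalence`, `achieved_or`
#'   and `marginal_dev`
#' @export
penetrance_table <- function(loci, cells, maf = 0.3) {
  k <- length(loci)
  stopifnot(k >= 1, length(cells) == 3^k)
  if (any(cells < 0 | cells > 1)) stop("penetrance cells must lie in [0, 1]")
  maf <- rep_len(maf, k)
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  tab <- list(loci = loci, cells = as.numeric(cells), maf = maf)
  class(tab) <- "penetrance_table"
  tab$prevalence <- table_prevalence(tab)
  tab$marginal_dev <- table_marginal_dev(tab)
  tab$achieved_or <- table_achieved_or(tab)
  tab
}

#' @export
model_loci.penetrance_table <- function(model) model$loci

# HWE genotype probabilities for one locus at minor allele frequency p,
# dosage order 0/1/2.
hwe_genotype_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# Cell weights (HWE product across loci) for a k-locus table, in cell order.
table_cell_weights <- function(maf) {
  w <- 1
  for (p in maf) w <- as.numeric(outer(w, hwe_genotype_probs(p)))
  w
}

# Genotype configurations (3^k x k matrix) in cell order.
table_cell_genotypes <- function(k) {
  as.matrix(expand.grid(rep(list(0:2), k)))[, , drop = FALSE]
}

table_prevalence <- function(table) {
  sum(table_cell_weights(table$maf) * table$cells)
}

#' Single-locus marginal penetrances and prevalence of a table
#'
#' The marginal penetrance of locus `l` at genotype `g` is the HWE-weighted
#' mean penetrance over all cells with that genotype at `l`; a purely
#' epistatic table has all marginals equal to the prevalence, so no locus
#' shows a single-locus main effect.
#'
#' @param table a `penetrance_table`
#' @return list with `marginals` (k x 3 matrix, loci x genotype 0/1/2) and
#'   `prevalence`
#' @export
table_marginals <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  k <- length(table$loci)
  w <- table_cell_weights(table$maf)
  gt <- table_cell_genotypes(k)
  marg <- matrix(NA_real_, nrow = k, ncol = 3,
                 dimnames = list(table$loci, c("g0", "g1", "g2")))
  for (l in seq_len(k)) {
    for (g in 0:2) {
      sel <- gt[, l] == g
      marg[l, g + 1L] <- sum(w[sel] * table$cells[sel]) / sum(w[sel])
    }
  }
  list(marginals = marg, prevalence = sum(w * table$cells))
}

# Max absolute deviation of any single-locus marginal from the prevalence.
table_marginal_dev <- function(table) {
  m <- table_marginals(table)
  max(abs(m$marginals - m$prevalence))
}

#' Achieved odds ratio of a penetrance table
#'
#' Odds of disease in the high-risk genotype class (cells with penetrance
#' strictly above the HWE-weighted table mean) versus all remaining cells,
#' cell probabilities weighted by HWE genotype frequencies. This matches the
#' high/low-risk dichotomy multifactor dimensionality reduction applies to
#' the same cells, and is computed by exact enumeration over the `3^k` cells.
#'
#' @param table a `penetrance_table`
#' @return the odds ratio; `NA` if every cell falls on one side of the mean
#' @export
table_achieved_or <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  w <- table_cell_weights(table$maf)
  prev <- sum(w * table$cells)
  hi <- table$cells > prev
  if (!any(hi) || all(hi)) return(NA_real_)
  pH <- sum(w[hi] * table$cells[hi]) / sum(w[hi])
  pL <- sum(w[!hi] * table$cells[!hi]) / sum(w[!hi])
  if (pH >= 1 || pL <= 0) return(Inf)
  (pH / (1 - pH)) / (pL / (1 - pL))
}

# Penetrance lookup for dosage genotypes at the table's loci.
table_penetrance <- function(table, genotypes) {
  G <- as_dosage_matrix(genotypes)
  missing <- setdiff(table$loci, colnames(G))
  if (length(missing))
    stop("genotypes lack table locus/loci: ", paste(missing, collapse = ", "))
  idx <- rep(1L, nrow(G))
  mult <- 1L
  for (l in table$loci) {
    idx <- idx + as.integer(G[, l]) * mult
    mult <- mult * 3L
  }
  table$cells[idx]
}

#' @export
print.penetrance_table <- function(x, ...) {
  cat(sprintf("penetrance_table: %d loci (%s), maf %s\n",
              length(x$loci), paste(x$loci, collapse = ", "),
              paste(sprintf("%.3f", x$maf), collapse = "/")))
  cat(sprintf("  prevalence %.4f, achieved OR %.4f, max marginal deviation %.2e\n",
              x$prevalence, x$achieved_or, x$marginal_dev))
  invisible(x)
}

#' Configuration for the genetic-algorithm penetrance-table search
#'
#' @param target_or target odds ratio of the high-risk genotype class (> 1)
#' @param maf per-locus minor allele frequency (scalar or length `n_loci`)
#' @param n_loci number of interacting loci (default 3)
#' @param population_size GA population size
#' @param generations number of GA generations
#' @param mutation_rate per-cell mutation probability
#' @param mutation_sd standard deviation of Gaussian cell mutations
#' @param marginal_tolerance maximum acceptable marginal deviation
#' @param target_prevalence anchor for the HWE-weighted table mean (the
#'   population prevalence the table should imply), default 0.10
#' @param weights fitness weights `c(or, marginal, prevalence)`
#' @param seed integer seed
#' @return an `epistatic_search_config`
#' @export
epistatic_search_config <- function(target_or = 4, maf = 0.3, n_loci = 3L,
                                    population_size = 150L, generations = 400L,
                                    mutation_rate = 0.15, mutation_sd = 0.02,
                                    marginal_tolerance = 0.01,
                                    target_prevalence = 0.10,
                                    weights = c(or = 1, marginal = 10, prevalence = 1),
                                    seed = 1L) {
  stopifnot(target_or > 1, marginal_tolerance > 0,
            population_size >= 4, generations >= 1,
            target_prevalence > 0, target_prevalence < 1)
  cfg <- list(target_or = target_or, maf = rep_len(maf, n_loci), n_loci = as.integer(n_loci),
              population_size = as.integer(population_size),
              generations = as.integer(generations),
              mutation_rate = mutation_rate, mutation_sd = mutation_sd,
              marginal_tolerance = marginal_tolerance,
              target_prevalence = target_prevalence,
              weights = weights, seed = as.integer(seed))
  class(cfg) <- "epistatic_search_config"
  cfg
}

# Fitness of a population of candidate tables (rows of P, one cell vector
# each): -w1*|log(OR/target)| - w2*marginal_dev - w3*|prevalence - target|.
# Undefined OR (single-class tables) incurs a large penalty.
ga_fitness <- function(P, w, Wm, cfg) {
  prev <- as.numeric(P %*% w)
  marg <- P %*% Wm                     # pop x (3k) conditional marginals
  dev <- apply(abs(marg - prev), 1L, max)
  A <- P > prev                        # high-risk class indicator per row
  massH <- as.numeric(A %*% w)
  edH <- as.numeric((A * P) %*% w)
  massL <- 1 - massH
  edL <- prev - edH
  pH <- edH / massH
  pL <- edL / massL
  or <- (pH / (1 - pH)) / (pL / (1 - pL))
  bad <- !is.finite(or) | or <= 0 | massH == 0 | massL == 0
  or_pen <- abs(log(ifelse(bad, NA, or) / cfg$target_or))
  or_pen[bad] <- 50
  wts <- cfg$weights
  fit <- -wts[[1L]] * or_pen - wts[[2L]] * dev -
    wts[[3L]] * abs(prev - cfg$target_prevalence)
  list(fitness = fit, or = or, dev = dev, prev = prev)
}

#' Generate a purely epistatic penetrance table by genetic-algorithm search
#'
#' Searches the `3^k`-cell penetrance space for a table whose single-locus
#' marginal penetrances are all (nearly) equal to the prevalence -- so no
#' locus shows a main effect -- while the odds ratio of the high-risk
#' genotype class hits a target value. Real-coded GA with tournament
#' selection, uniform crossover, Gaussian mutation, elitism, and a
#' marginal-projection repair operator (offspring are occasionally projected
#' onto the linear subspace of zero-main-effect tables).
#'
#' @param config an [epistatic_search_config()]
#' @param loci marker ids for the table's loci (defaults to `locus1..k`)
#' @return a `penetrance_table` with the GA trace in attribute `"trace"`
#'   (best fitness, OR, marginal deviation and prevalence per generation).
#'   If the search does not reach `marginal_tolerance` within the generation
#'   budget, a condition of class `phenobench_convergence_error` is signalled
#'   carrying the best table found in its `$table` field.
#' @examples
#' \donttest{
#' cfg <- epistatic_search_config(target_or = 4, maf = 0.3, seed = 7)
#' tab <- generate_epistatic_table(cfg)
#' tab$achieved_or
#' }
#' @export
generate_epistatic_table <- function(config, loci = NULL) {
  stopifnot(inherits(config, "epistatic_search_config"))
  k <- config$n_loci
  nc <- 3^k
  if (is.null(loci)) loci <- paste0("locus", seq_len(k))
  stopifnot(length(loci) == k)
  w <- table_cell_weights(config$maf)
  gt <- table_cell_genotypes(k)
  # Wm: cell -> per-(locus, genotype) conditional HWE weights, 3k columns
  Wm <- matrix(0, nrow = nc, ncol = 3L * k)
  for (l in seq_len(k)) for (g in 0:2) {
    sel <- gt[, l] == g
    col <- (l - 1L) * 3L + g + 1L
    Wm[sel, col] <- w[sel] / sum(w[sel])
  }
  # projection onto the zero-marginal subspace: constraints C %*% cells = 0
  C <- t(Wm) - matrix(w, nrow = 3L * k, ncol = nc, byrow = TRUE)
  sv <- svd(C)
  pos <- sv$d > max(sv$d) * 1e-10
  Cpinv <- sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
  project_marginals <- function(P) {
    P - t(Cpinv %*% (C %*% t(P)))
  }

  np <- config$population_size
  trace <- data.frame(generation = integer(0), fitness = numeric(0),
                      or = numeric(0), marginal_dev = numeric(0),
                      prevalence = numeric(0))
  res <- local_rng(config$seed, {
    P <- matrix(stats::runif(np * nc, 0, min(1, 2.5 * config$target_prevalence)),
                nrow = np, ncol = nc)
    for (gen in seq_len(config$generations)) {
      sc <- ga_fitness(P, w, Wm, config)
      ord <- order(sc$fitness, decreasing = TRUE)
      best <- ord[1L]
      trace[gen, ] <- list(gen, sc$fitness[best], sc$or[best],
                           sc$dev[best], sc$prev[best])
      if (gen == config$generations) break
      # tournament selection (size 2)
      t1 <- sample.int(np, np, replace = TRUE)
      t2 <- sample.int(np, np, replace = TRUE)
      parent <- ifelse(sc$fitness[t1] >= sc$fitness[t2], t1, t2)
      mates <- parent[sample.int(np)]
      # uniform crossover
      mask <- matrix(stats::runif(np * nc) < 0.5, np, nc)
      Q <- ifelse(mask, P[parent, ], P[mates, ])
      # Gaussian mutation
      mut <- matrix(stats::runif(np * nc) < config$mutation_rate, np, nc)
      Q[mut] <- Q[mut] + stats::rnorm(sum(mut), 0, config$mutation_sd)
      # marginal-projection repair on a fraction of offspring
      rep_rows <- stats::runif(np) < 0.25
      if (any(rep_rows))
        Q[rep_rows, ] <- project_marginals(Q[rep_rows, , drop = FALSE])
      Q[Q < 0] <- 0; Q[Q > 1] <- 1
      # elitism: keep the two best unchanged
      Q[1L, ] <- P[ord[1L], ]
      Q[2L, ] <- P[ord[2L], ]
      P <- Q
    }
    list(cells = P[best, ], final = ga_fitness(P, w, Wm, config))
  })
  tab <- penetrance_table(loci, res$cells, config$maf)
  attr(tab, "trace") <- trace
  attr(tab, "config") <- config
  if (tab$marginal_dev > config$marginal_tolerance) {
    cond <- structure(
      class = c("phenobench_convergence_error", "error", "condition"),
      list(message = sprintf(
        "GA did not reach marginal tolerance %.3g (best: %.3g); best table attached",
        config$marginal_tolerance, tab$marginal_dev),
        call = sys.call(-1), table = tab))
    stop(cond)
  }
  tab
}

#' Write / read a penetrance table as plain text
#'
#' The format is one row per cell (`k` genotype columns + penetrance), with
#' `#`-prefixed header lines recording loci, MAF, achieved OR, marginal
#' deviation and prevalence.
#'
#' @param table a `penetrance_table`
#' @param path file path
#' @return `write_penetrance_table` returns `path` invisibly;
#'   `read_penetrance_table` returns the reconstructed `penetrance_table`
#' @export
write_penetrance_table <- function(table, path) {
  stopifnot(inherits(table, "penetrance_table"))
  k <- length(table$loci)
  hdr <- c(
    paste0("# loci: ", paste(table$loci, collapse = " ")),
    paste0("# maf: ", paste(format(table$maf, digits = 10), collapse = " ")),
    paste0("# achieved_or: ", format(table$achieved_or, digits = 10)),
    paste0("# marginal_dev: ", format(table$marginal_dev, digits = 10)),
    paste0("# prevalence: ", format(table$prevalence, digits = 10))
  )
  gt <- table_cell_genotypes(k)
  body <- apply(cbind(gt, format(table$cells, digits = 15)), 1L, paste, collapse = "\t")
  writeLines(c(hdr, paste(c(paste0("g", seq_len(k)), "penetrance"), collapse = "\t"), body),
             path)
  invisible(path)
}

#' @rdname write_penetrance_table
#' @export
read_penetrance_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, ": "), "", hdr[startsWith(hdr, paste0("# ", key, ":"))])
  loci <- strsplit(get("loci"), " ")[[1L]]
  maf <- as.numeric(strsplit(get("maf"), " ")[[1L]])
  body <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE, sep = "\t")
  k <- length(loci)
  idx <- 1L + as.matrix(body[, seq_len(k), drop = FALSE]) %*% 3^(seq_len(k) - 1L)
  cells <- numeric(3^k)
  cells[idx] <- body$penetrance
  penetrance_table(loci, cells, maf)
}
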