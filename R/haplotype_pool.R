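#' Build a block-structured haplotype pool
#'
#' Emulates the linkage-disequilibrium structure of a simulated chromosome
#' with a block-haplotype model: within each LD block, `pool_size` haplotypes
#' are generated by a first-order latent-uniform copula chain, so that each
#' marker keeps exactly its target minor allele frequency while adjacent
#' markers within a block are correlated (correlation decaying geometrically
#' with distance at rate `ld_decay`). Blocks are mutually independent, so
#' across-block r-squared is ~0. Individuals are later sampled as two
#' independent haplotype draws per block, which puts every marker in
#' Hardy-Weinberg equilibrium at the pool's allele frequencies.
#'
#' @param markers a `marker_map` from [build_marker_map()]
#' @param ld_decay chain persistence in `[0, 1]`: 0 gives independent markers,
#'   1 gives a single latent draw per block (perfect LD for equal-MAF markers)
#' @param pool_size number of haplotypes per block (>= 2)
#' @param seed integer seed
#' @return a `haplotype_pool`: list with `haplotypes` (pool_size x n_markers
#'   0/1 matrix, 1 = minor allele), `weights` (per-haplotype sampling
#'   probability, uniform by default, summing to 1 within each block),
#'   `markers`, and `blocks` (list of column indices per block)
#' @export
build_haplotype_pool <- function(markers, ld_decay = 0.7, pool_size = 200L, seed = 1L) {
  stopifnot(inherits(markers, "marker_map"))
  if (!is.numeric(ld_decay) || ld_decay < 0 || ld_decay > 1)
    stop("ld_decay must lie in [0, 1]")
  if (pool_size < 2) stop("pool_size must be >= 2")
  pool_size <- as.integer(pool_size)
  M <- nrow(markers)
  blocks <- split(seq_len(M), markers$block_id)
  H <- matrix(0L, nrow = pool_size, ncol = M)
  local_rng(seed, {
    for (cols in blocks) {
      u <- stats::runif(pool_size)
      for (k in seq_along(cols)) {
        if (k > 1L) {
          refresh <- stats::runif(pool_size) >= ld_decay
          u[refresh] <- stats::runif(sum(refresh))
        }
        H[, cols[k]] <- as.integer(u < markers$maf[cols[k]])
      }
    }
  })
  colnames(H) <- markers$id
  pool <- list(
    haplotypes = H,
    weights = rep(1 / pool_size, pool_size),
    markers = markers,
    blocks = blocks
  )
  class(pool) <- "haplotype_pool"
  pool
}

#' Weighted allele frequencies of a haplotype pool
#'
#' @param pool a `haplotype_pool`
#' @return named numeric vector of minor-allele frequencies, one per marker
#' @export
pool_allele_freq <- function(pool) {
  drop(crossprod(pool$weights, pool$haplotypes))
}

#' Pairwise linkage disequilibrium (r-squared) between two markers
#'
#' Computed exactly from the weighted haplotype pool.
#'
#' @param pool a `haplotype_pool`
#' @param i,j marker ids or 1-based column indices
#' @return squared haplotype correlation; `NA` if either marker is monomorphic
#' @export
ld_r2 <- function(pool, i, j) {
  if (is.character(i)) i <- marker_index(pool$markers, i)
  if (is.character(j)) j <- marker_index(pool$markers, j)
  w <- pool$weights
  hi <- pool$haplotypes[, i]
  hj <- pool$haplotypes[, j]
  pi <- sum(w * hi); pj <- sum(w * hj)
  v <- pi * (1 - pi) * pj * (1 - pj)
  if (v == 0) return(NA_real_)
  d <- sum(w * hi * hj) - pi * pj
  d^2 / v
}

# Draw n haplotypes from the pool: a n x n_blocks matrix of pool row indices.
# Consumes the active RNG stream.
draw_hap_rows <- function(pool, n) {
  nb <- length(pool$blocks)
  matrix(sample.int(nrow(pool$haplotypes), n * nb, replace = TRUE,
                    prob = pool$weights * nrow(pool$haplotypes)),
         nrow = n, ncol = nb)
}

# Materialise genotype columns for given blocks from two hap-row index
# matrices (n x n_blocks each). Returns an n x |cols| integer matrix.
rows_to_genotypes <- function(pool, rowsA, rowsB, block_ids = seq_along(pool$blocks)) {
  cols <- unlist(pool$blocks[block_ids], use.names = FALSE)
  n <- nrow(rowsA)
  G <- matrix(0L, nrow = n, ncol = length(cols))
  off <- 0L
  for (b in block_ids) {
    bc <- pool$blocks[[b]]
    G[, off + seq_along(bc)] <- pool$haplotypes[rowsA[, b], bc, drop = FALSE] +
      pool$haplotypes[rowsB[, b], bc, drop = FALSE]
    off <- off + length(bc)
  }
  colnames(G) <- colnames(pool$haplotypes)[cols]
  G
}

#' Sample unrelated individual genotypes from a haplotype pool
#'
#' Each individual is the sum of two independent haplotype draws (one per
#' block per haplotype), coded as minor-allele dosage 0/1/2.
#'
#' @param pool a `haplotype_pool`
#' @param n_individuals number of individuals (>= 1)
#' @param seed integer seed
#' @return a `genotype_matrix`: list with `genotypes` (n x M integer matrix,
#'   marker ids as column names), `markers`, `individual_ids`
#' @export
sample_genotypes <- function(pool, n_individuals, seed = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"), n_individuals >= 1)
  n <- as.integer(n_individuals)
  G <- local_rng(seed, {
    rowsA <- draw_hap_rows(pool, n)
    rowsB <- draw_hap_rows(pool, n)
    rows_to_genotypes(pool, rowsA, rowsB)
  })
  # restore chromosome order (blocks are contiguous, so this is already ordered)
  new_genotype_matrix(G, pool$markers)
}

new_genotype_matrix <- function(G, markers, ids = NULL) {
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(G)))
  rownames(G) <- NULL
  gm <- list(genotypes = G, markers = markers, individual_ids = ids)
  class(gm) <- "genotype_matrix"
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' Sample a parent-offspring trio with transmission records
#'
#' Parents are two independent haplotype draws each; the child receives one
#' whole haplotype from each parent, chosen uniformly. The record keeps which
#' parental haplotype was transmitted, which the transmission disequilibrium
#' test consumes directly.
#'
#' @param pool a `haplotype_pool`
#' @param seed integer seed
#' @return list with `father`, `mother` (2 x M haplotype matrices),
#'   `father_genotype`, `mother_genotype`, `child_genotype` (dosage vectors),
#'   and `transmitted` (length-2 integer: which haplotype of father, mother)
#' @export
sample_trio <- function(pool, seed = 1L) {
  stopifnot(inherits(pool, "haplotype_pool"))
  local_rng(seed, {
    fa <- rbind(hap_vector(pool, draw_hap_rows(pool, 1L)),
                hap_vector(pool, draw_hap_rows(pool, 1L)))
    mo <- rbind(hap_vector(pool, draw_hap_rows(pool, 1L)),
                hap_vector(pool, draw_hap_rows(pool, 1L)))
    tf <- sample.int(2L, 1L)
    tm <- sample.int(2L, 1L)
    list(
      father = fa, mother = mo,
      father_genotype = fa[1L, ] + fa[2L, ],
      mother_genotype = mo[1L, ] + mo[2L, ],
      child_genotype = fa[tf, ] + mo[tm, ],
      transmitted = c(father = tf, mother = tm)
    )
  })
}

# Materialise one haplotype (length-M 0/1 vector) from a 1 x n_blocks row-index matrix.
hap_vector <- function(pool, rows) {
  M <- ncol(pool$haplotypes)
  h <- integer(M)
  for (b in seq_along(pool$blocks)) {
    bc <- pool$blocks[[b]]
    h[bc] <- pool$haplotypes[rows[1L, b], bc]
  }
  names(h) <- colnames(pool$haplotypes)
  h
}

# Exact joint genotype distribution of a set of loci under the pool.
# Loci in different blocks are independent; within a block the joint law is
# enumerated from the weighted haplotype pool. Returns a data.frame with one
# column per locus (dosage 0/1/2) plus `prob`.
locus_joint_distribution <- function(pool, loci) {
  idx <- marker_index(pool$markers, loci)
  blocks <- pool$markers$block_id[idx]
  parts <- lapply(unique(blocks), function(b) {
    cols <- idx[blocks == b]
    hap <- pool$haplotypes[, cols, drop = FALSE]
    w <- pool$weights
    # haplotype-pattern distribution within the block
    key <- apply(hap, 1L, paste, collapse = ",")
    pw <- tapply(w, key, sum)
    pats <- do.call(rbind, lapply(strsplit(names(pw), ","), as.integer))
    # genotype = sum of two independent haplotype patterns
    np <- nrow(pats)
    gi <- expand.grid(a = seq_len(np), b = seq_len(np))
    gmat <- pats[gi$a, , drop = FALSE] + pats[gi$b, , drop = FALSE]
    gp <- as.numeric(pw[gi$a] * pw[gi$b])
    gkey <- apply(gmat, 1L, paste, collapse = ",")
    agg <- tapply(gp, gkey, sum)
    gpat <- do.call(rbind, lapply(strsplit(names(agg), ","), as.integer))
    colnames(gpat) <- pool$markers$id[cols]
    list(pat = gpat, prob = as.numeric(agg))
  })
  joint <- parts[[1L]]
  if (length(parts) > 1L) {
    for (p in parts[-1L]) {
      ia <- rep(seq_len(nrow(joint$pat)), times = nrow(p$pat))
      ib <- rep(seq_len(nrow(p$pat)), each = nrow(joint$pat))
      joint <- list(pat = cbind(joint$pat[ia, , drop = FALSE], p$pat[ib, , drop = FALSE]),
                    prob = joint$prob[ia] * p$prob[ib])
    }
  }
  out <- as.data.frame(joint$pat)
  out <- out[, loci, drop = FALSE]
  out$prob <- joint$prob
  out
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d markers (%d blocks)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$blocks)))
  invisible(x)
}
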