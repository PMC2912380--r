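#' Build a synthetic chromosome marker map with LD-block structure
#'
#' Markers are biallelic SNPs labelled `RL0-<index>` (0-based index along the
#' chromosome). The chromosome is partitioned into contiguous LD blocks whose
#' sizes are drawn uniformly from `block_size_range`; each marker's minor
#' allele frequency is drawn uniformly from `maf_range`.
#'
#' @param n_markers number of markers on the chromosome (>= 1)
#' @param block_size_range integer pair, inclusive range of block sizes
#' @param maf_range numeric pair within (0, 0.5], range for minor allele
#'   frequencies
#' @param seed integer seed; the map is deterministic given the seed
#' @return a `marker_map`: a data.frame with columns `id`, `index` (0-based),
#'   `maf`, `block_id`
#' @examples
#' mm <- build_marker_map(50, seed = 1)
#' head(mm)
#' @export
build_marker_map <- function(n_markers, block_size_range = c(5L, 15L),
                             maf_range = c(0.05, 0.5), seed = 1L) {
  if (!is.numeric(n_markers) || length(n_markers) != 1L || n_markers < 1)
    stop("n_markers must be a positive count")
  n_markers <- as.integer(n_markers)
  if (length(block_size_range) != 2L || any(block_size_range < 1) ||
      block_size_range[1] > block_size_range[2])
    stop("invalid block_size_range")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")

  local_rng(seed, {
    sizes <- integer(0)
    total <- 0L
    while (total < n_markers) {
      s <- sample(seq.int(block_size_range[1], block_size_range[2]), 1L)
      sizes <- c(sizes, s)
      total <- total + s
    }
    # trim the last block so blocks exactly partition the chromosome
    sizes[length(sizes)] <- sizes[length(sizes)] - (total - n_markers)
    if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
    block_id <- rep.int(seq_along(sizes), sizes)
    maf <- stats::runif(n_markers, maf_range[1], maf_range[2])
    mm <- data.frame(
      id = paste0("RL0-", seq_len(n_markers) - 1L),
      index = seq_len(n_markers) - 1L,
      maf = maf,
      block_id = block_id,
      stringsAsFactors = FALSE
    )
    class(mm) <- c("marker_map", "data.frame")
    mm
  })
}

#' Override the minor allele frequency of selected markers
#'
#' Used to pin disease loci to a stated MAF (e.g. drawn in `[0.30, 0.45]` so
#' a disease SNP is a common variant) before the haplotype pool is built.
#'
#' @param markers a `marker_map`
#' @param loci character vector of marker ids
#' @param maf replacement MAF(s), recycled to `length(loci)`
#' @return the modified `marker_map`
#' @export
set_marker_maf <- function(markers, loci, maf) {
  idx <- match(loci, markers$id)
  if (anyNA(idx)) stop("unknown marker id(s): ", paste(loci[is.na(idx)], collapse = ", "))
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  markers$maf[idx] <- rep_len(maf, length(idx))
  markers
}

marker_index <- function(markers, loci) {
  idx <- match(loci, markers$id)
  if (anyNA(idx)) stop("unknown marker id(s): ", paste(loci[is.na(idx)], collapse = ", "))
  idx
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers in %d LD blocks, MAF range [%.3f, %.3f]\n",
              nrow(x), length(unique(x$block_id)), min(x$maf), max(x$maf)))
  invisible(x)
}
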