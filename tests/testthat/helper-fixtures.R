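# Shared fixtures, built in code at test time.

# A small chromosome with three pinned common loci, used as an EPI-style toy.
toy_pool <- function(n_markers = 60L, pinned = c("RL0-10", "RL0-25", "RL0-40"),
                     maf = 0.3, pool_size = 400L, ld_decay = 0.7, seed = 1L) {
  mm <- build_marker_map(n_markers, seed = child_seed(seed, "map"))
  mm <- set_marker_maf(mm, pinned, maf)
  build_haplotype_pool(mm, ld_decay = ld_decay, pool_size = pool_size,
                       seed = child_seed(seed, "pool"))
}

# Purely epistatic table fitted at the toy pool's empirical frequencies.
toy_epi_table <- function(pool, loci = c("RL0-10", "RL0-25", "RL0-40"),
                          target_or = 4, seed = 7L) {
  fr <- pool_allele_freq(pool)[loci]
  cfg <- epistatic_search_config(target_or = target_or, maf = pmin(fr, 0.5),
                                 seed = seed)
  generate_epistatic_table(cfg, loci = loci)
}

# Build a single-marker cc_dataset from genotype count vectors (cases r,
# controls s, each counts of dosage 0/1/2).
cc_from_counts <- function(r, s) {
  G <- matrix(c(rep(0:2, r), rep(0:2, s)), ncol = 1L)
  colnames(G) <- "M1"
  mm <- data.frame(id = "M1", index = 0L, maf = 0.3, block_id = 1L,
                   stringsAsFactors = FALSE)
  class(mm) <- c("marker_map", "data.frame")
  phenobench:::new_cc_dataset(
    phenobench:::new_genotype_matrix(G, mm),
    c(rep(1L, sum(r)), rep(0L, sum(s))))
}

# A cc_dataset straight from explicit genotype matrix + status.
cc_from_matrix <- function(G, status) {
  mm <- data.frame(id = colnames(G), index = seq_len(ncol(G)) - 1L,
                   maf = 0.3, block_id = 1L, stringsAsFactors = FALSE)
  class(mm) <- c("marker_map", "data.frame")
  phenobench:::new_cc_dataset(
    phenobench:::new_genotype_matrix(G, mm), as.integer(status))
}

# Flat-penetrance table over 3 loci.
flat_table <- function(p, loci = c("A", "B", "C"), maf = 0.3) {
  penetrance_table(loci, rep(p, 27), maf)
}
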