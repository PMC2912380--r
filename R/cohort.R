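#' Pooling design for case-control sampling
#'
#' The benchmark design pools many small independently sampled case-control
#' datasets to damp sampling fluctuation: by default 50 replicates of
#' 200 cases + 200 controls, i.e. 20,000 individuals per pooled dataset.
#'
#' @param n_replicates number of pooled sub-datasets (default 50)
#' @param cases_per_replicate,controls_per_replicate per-replicate quotas
#'   (default 200 each)
#' @param seed integer seed
#' @return a `pool_spec`
#' @export
pool_spec <- function(n_replicates = 50L, cases_per_replicate = 200L,
                      controls_per_replicate = 200L, seed = 1L) {
  stopifnot(n_replicates >= 1, cases_per_replicate >= 0, controls_per_replicate >= 0)
  s <- list(n_replicates = as.integer(n_replicates),
            cases_per_replicate = as.integer(cases_per_replicate),
            controls_per_replicate = as.integer(controls_per_replicate),
            seed = as.integer(seed))
  class(s) <- "pool_spec"
  s
}

# Constant candidate batch size for rejection sampling. Keeping it constant
# makes the accepted-case stream a stable prefix in the quota (the first j
# accepted individuals are identical whatever the final quota), which the
# PM2 injector relies on to couple phenocopy levels by common random numbers.
CC_BATCH <- 512L

new_cc_dataset <- function(gm, status, phenocopy_flag = NULL, replicate_id = NULL) {
  n <- nrow(gm$genotypes)
  if (is.null(phenocopy_flag)) phenocopy_flag <- rep("none", n)
  if (is.null(replicate_id)) replicate_id <- rep(1L, n)
  ds <- list(genotypes = gm, status = as.integer(status),
             phenocopy_flag = phenocopy_flag, replicate_id = as.integer(replicate_id))
  class(ds) <- "cc_dataset"
  ds
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("cc_dataset: %d individuals (%d cases / %d controls) x %d markers; %d phenocopies\n",
              length(x$status), sum(x$status == 1L), sum(x$status == 0L),
              ncol(x$genotypes$genotypes), sum(x$phenocopy_flag != "none")))
  invisible(x)
}

# Draw genotypes at the model's causal blocks only, assign status, and keep
# accepted hap-row indices; other blocks are filled afterwards for accepted
# individuals only (valid because LD blocks are mutually independent).
reject_sample <- function(pool, model, n_affected, n_unaffected, max_draws = 1e6) {
  loci <- model_loci(model)
  bneed <- sort(unique(pool$markers$block_id[marker_index(pool$markers, loci)]))
  nb <- length(pool$blocks)
  accA <- vector("list", 0L); accB <- vector("list", 0L); accy <- integer(0)
  got_a <- 0L; got_u <- 0L; drawn <- 0L
  while (got_a < n_affected || got_u < n_unaffected) {
    if (drawn >= max_draws)
      stop("rejection sampling exceeded ", max_draws,
           " draws (degenerate penetrance model?)")
    rowsA <- draw_hap_rows_at(pool, CC_BATCH, bneed)
    rowsB <- draw_hap_rows_at(pool, CC_BATCH, bneed)
    G <- rows_to_genotypes(pool, expand_rows(rowsA, bneed, nb),
                           expand_rows(rowsB, bneed, nb), bneed)
    p <- penetrance_of(model, G)
    y <- as.integer(stats::rbinom(CC_BATCH, 1L, p))
    keep_a <- which(y == 1L)[seq_len(min(sum(y == 1L), n_affected - got_a))]
    keep_u <- which(y == 0L)[seq_len(min(sum(y == 0L), n_unaffected - got_u))]
    keep <- c(keep_a, keep_u)
    if (length(keep)) {
      accA[[length(accA) + 1L]] <- rowsA[keep, , drop = FALSE]
      accB[[length(accB) + 1L]] <- rowsB[keep, , drop = FALSE]
      accy <- c(accy, y[keep])
    }
    got_a <- got_a + length(keep_a)
    got_u <- got_u + length(keep_u)
    drawn <- drawn + CC_BATCH
  }
  A <- do.call(rbind, accA)
  B <- do.call(rbind, accB)
  ord <- order(-accy)  # affected first, in acceptance order (stable)
  list(rowsA = A[ord, , drop = FALSE], rowsB = B[ord, , drop = FALSE],
       status = accy[ord], blocks = bneed)
}

draw_hap_rows_at <- function(pool, n, block_ids) {
  matrix(sample.int(nrow(pool$haplotypes), n * length(block_ids), replace = TRUE,
                    prob = pool$weights * nrow(pool$haplotypes)),
         nrow = n, ncol = length(block_ids))
}

# Place needed-block row indices into a full n x n_blocks matrix (other
# columns 0; only the needed columns are ever read downstream).
expand_rows <- function(rows, block_ids, nb) {
  out <- matrix(1L, nrow = nrow(rows), ncol = nb)
  out[, block_ids] <- rows
  out
}

# Fill the non-causal blocks with fresh draws and materialise the full
# genotype matrix for accepted individuals.
materialise_individuals <- function(pool, rowsA, rowsB, blocks) {
  n <- nrow(rowsA)
  nb <- length(pool$blocks)
  other <- setdiff(seq_len(nb), blocks)
  RA <- matrix(0L, n, nb); RB <- matrix(0L, n, nb)
  RA[, blocks] <- rowsA; RB[, blocks] <- rowsB
  if (length(other)) {
    RA[, other] <- draw_hap_rows_at(pool, n, other)
    RB[, other] <- draw_hap_rows_at(pool, n, other)
  }
  rows_to_genotypes(pool, RA, RB)
}

#' Rejection-sample a case-control dataset under a disease model
#'
#' Individuals are drawn from the haplotype pool, assigned affection status
#' by the model's penetrance, and routed to the case or control quota until
#' both are met (affected rows first).
#'
#' @param pool a `haplotype_pool`
#' @param model a `logistic_disease_model` or `penetrance_table`
#' @param n_cases,n_controls quotas (>= 0)
#' @param seed integer seed
#' @param max_draws rejection-sampling attempt cap (guards degenerate models)
#' @return a `cc_dataset` with `genotypes`, `status` (1 = case),
#'   `phenocopy_flag` (all `"none"`) and `replicate_id`
#' @export
sample_case_control <- function(pool, model, n_cases, n_controls, seed = 1L,
                                max_draws = 1e6) {
  stopifnot(inherits(pool, "haplotype_pool"), n_cases >= 0, n_controls >= 0)
  local_rng(seed, {
    rs <- reject_sample(pool, model, n_cases, n_controls, max_draws)
    G <- materialise_individuals(pool, rs$rowsA, rs$rowsB, rs$blocks)
    new_cc_dataset(new_genotype_matrix(G, pool$markers), rs$status)
  })
}

#' Build a pooled case-control dataset
#'
#' Concatenates `n_replicates` independent [sample_case_control()] draws,
#' recording which replicate each row came from. With the default design
#' (50 x (200 cases + 200 controls)) the pooled dataset holds 20,000
#' individuals.
#'
#' @param pool a `haplotype_pool`
#' @param model disease model
#' @param spec a [pool_spec()]
#' @return a pooled `cc_dataset`
#' @export
build_cc_pool <- function(pool, model, spec = pool_spec()) {
  stopifnot(inherits(spec, "pool_spec"))
  parts <- lapply(seq_len(spec$n_replicates), function(r) {
    sample_case_control(pool, model, spec$cases_per_replicate,
                        spec$controls_per_replicate,
                        seed = child_seed(spec$seed, paste0("cc-rep-", r)))
  })
  G <- do.call(rbind, lapply(parts, function(d) d$genotypes$genotypes))
  status <- unlist(lapply(parts, `[[`, "status"), use.names = FALSE)
  rep_id <- rep(seq_len(spec$n_replicates),
                each = spec$cases_per_replicate + spec$controls_per_replicate)
  new_cc_dataset(new_genotype_matrix(G, pool$markers), status,
                 replicate_id = rep_id)
}

#' Sample unaffected individuals as a population-control reservoir
#'
#' Used by the PM1 phenocopy injector, whose phenocopies are population
#' controls relabelled as affected. Drawing a fresh reservoir (rather than
#' reusing the dataset's own controls) avoids duplicate rows.
#'
#' @inheritParams sample_case_control
#' @param n number of unaffected individuals
#' @return a `genotype_matrix` of `n` unaffected individuals
#' @export
sample_population_controls <- function(pool, model, n, seed = 1L, max_draws = 1e6) {
  ds <- sample_case_control(pool, model, 0L, n, seed, max_draws)
  ds$genotypes
}

# ---- pedigrees ----------------------------------------------------------

default_family_configs <- function() {
  list(
    "1a2u"   = c(affected = 1L, unaffected = 2L, random = 0L),
    "3a1u"   = c(affected = 3L, unaffected = 1L, random = 0L),
    "2a2u3r" = c(affected = 2L, unaffected = 2L, random = 3L)
  )
}

new_ped_dataset <- function(pool, families, FA1, FA2, MO1, MO2, sibs) {
  ds <- list(pool = pool, families = families,
             FA1 = FA1, FA2 = FA2, MO1 = MO1, MO2 = MO2, sibs = sibs)
  class(ds) <- "ped_dataset"
  ds
}

#' @export
print.ped_dataset <- function(x, ...) {
  cat(sprintf("ped_dataset: %d families, %d individuals (%d sibs, %d affected); %d phenocopies\n",
              nrow(x$families), ped_n_individuals(x), nrow(x$sibs),
              sum(x$sibs$status == 1L), sum(x$sibs$flag != "none")))
  invisible(x)
}

#' Number of individuals (parents + sibs) in a pedigree dataset
#' @param ds a `ped_dataset`
#' @return integer count
#' @export
ped_n_individuals <- function(ds) 2L * nrow(ds$families) + nrow(ds$sibs)

# Vectorised ascertainment engine: draws sibships in batches at the causal
# blocks only and keeps those whose constrained sibs show exactly
# `n_affected` affected among `n_affected + n_unaffected`; random extra sibs
# are unconstrained. Runs under the active RNG.
ascertain_families <- function(pool, model, n_families, n_affected, n_unaffected,
                               n_random, max_draws = 1e6) {
  loci <- model_loci(model)
  bneed <- sort(unique(pool$markers$block_id[marker_index(pool$markers, loci)]))
  nb <- length(pool$blocks)
  ncon <- n_affected + n_unaffected
  nsib <- ncon + n_random
  if (nsib < 1L) {
    # parents only: accept immediately
    return(list(
      FA1 = draw_hap_rows_at(pool, n_families, bneed),
      FA2 = draw_hap_rows_at(pool, n_families, bneed),
      MO1 = draw_hap_rows_at(pool, n_families, bneed),
      MO2 = draw_hap_rows_at(pool, n_families, bneed),
      tf = matrix(integer(0), n_families, 0L), tm = matrix(integer(0), n_families, 0L),
      status = matrix(integer(0), n_families, 0L), blocks = bneed))
  }
  acc <- list(); got <- 0L; drawn <- 0L
  B <- 256L
  while (got < n_families) {
    if (drawn >= max_draws)
      stop("family ascertainment exceeded ", max_draws, " sibship draws")
    FA1 <- draw_hap_rows_at(pool, B, bneed); FA2 <- draw_hap_rows_at(pool, B, bneed)
    MO1 <- draw_hap_rows_at(pool, B, bneed); MO2 <- draw_hap_rows_at(pool, B, bneed)
    tf <- matrix(sample.int(2L, B * nsib, replace = TRUE), B, nsib)
    tm <- matrix(sample.int(2L, B * nsib, replace = TRUE), B, nsib)
    status <- matrix(0L, B, nsib)
    for (j in seq_len(nsib)) {
      RF <- FA1; sel <- tf[, j] == 2L; RF[sel, ] <- FA2[sel, ]
      RM <- MO1; sel <- tm[, j] == 2L; RM[sel, ] <- MO2[sel, ]
      Gj <- rows_to_genotypes(pool, expand_rows(RF, bneed, nb),
                              expand_rows(RM, bneed, nb), bneed)
      p <- penetrance_of(model, Gj)
      status[, j] <- stats::rbinom(B, 1L, p)
    }
    ok <- rowSums(status[, seq_len(ncon), drop = FALSE]) == n_affected
    keep <- which(ok)[seq_len(min(sum(ok), n_families - got))]
    if (length(keep))
      acc[[length(acc) + 1L]] <- list(FA1 = FA1[keep, , drop = FALSE],
                                      FA2 = FA2[keep, , drop = FALSE],
                                      MO1 = MO1[keep, , drop = FALSE],
                                      MO2 = MO2[keep, , drop = FALSE],
                                      tf = tf[keep, , drop = FALSE],
                                      tm = tm[keep, , drop = FALSE],
                                      status = status[keep, , drop = FALSE])
    got <- got + length(keep)
    drawn <- drawn + B
  }
  bind <- function(name) do.call(rbind, lapply(acc, `[[`, name))
  list(FA1 = bind("FA1"), FA2 = bind("FA2"), MO1 = bind("MO1"), MO2 = bind("MO2"),
       tf = bind("tf"), tm = bind("tm"), status = bind("status"), blocks = bneed)
}

#' Sample one ascertained nuclear family
#'
#' Rejection-samples sibships until the constrained sibs show exactly the
#' required affected/unaffected pattern. "Random" extra sibs carry a status
#' drawn from the model with no ascertainment constraint. Parent affection
#' status is recorded as unknown.
#'
#' @param pool a `haplotype_pool`
#' @param model disease model
#' @param n_affected_sibs,n_unaffected_sibs constrained sib counts
#' @param n_random_sibs unconstrained extra sibs
#' @param seed integer seed
#' @return a single-family `ped_dataset`
#' @export
sample_family <- function(pool, model, n_affected_sibs, n_unaffected_sibs,
                          n_random_sibs = 0L, seed = 1L) {
  stopifnot(n_affected_sibs >= 0, n_unaffected_sibs >= 0, n_random_sibs >= 0)
  label <- sprintf("%da%du%dr", n_affected_sibs, n_unaffected_sibs, n_random_sibs)
  build_pedigree_custom(pool, model,
                        configs = stats::setNames(
                          list(c(affected = as.integer(n_affected_sibs),
                                 unaffected = as.integer(n_unaffected_sibs),
                                 random = as.integer(n_random_sibs))), label),
                        families_per_config = 1L, n_replicates = 1L, seed = seed)
}

#' Build a pooled ascertained pedigree dataset
#'
#' Per replicate, `families_per_config` (default 25) families of each of the
#' three study configurations (1 affected + 2 unaffected sibs; 3 affected +
#' 1 unaffected; 2 affected + 2 unaffected + 3 random extra sibs) are
#' ascertained and pooled. With 50 replicates this yields
#' 50 x 25 x (5 + 6 + 9) = 25,000 individuals, parents included.
#'
#' @param pool a `haplotype_pool`
#' @param model disease model
#' @param n_replicates number of replicates pooled (default 50)
#' @param seed integer seed
#' @param configs named list of family configurations (integer vectors with
#'   `affected`, `unaffected`, `random`)
#' @param families_per_config families per configuration per replicate
#' @return a `ped_dataset`
#' @export
build_pedigree_pool <- function(pool, model, n_replicates = 50L, seed = 1L,
                                configs = default_family_configs(),
                                families_per_config = 25L) {
  build_pedigree_custom(pool, model, configs, families_per_config,
                        n_replicates, seed)
}

build_pedigree_custom <- function(pool, model, configs, families_per_config,
                                  n_replicates, seed) {
  nb <- length(pool$blocks)
  fam_rows <- list(); sib_rows <- list()
  FA1 <- FA2 <- MO1 <- MO2 <- list()
  fam_counter <- 0L
  for (r in seq_len(n_replicates)) {
    for (cfg_name in names(configs)) {
      cfg <- configs[[cfg_name]]
      res <- local_rng(child_seed(seed, paste0("ped-", r, "-", cfg_name)), {
        a <- ascertain_families(pool, model, families_per_config,
                                cfg[["affected"]], cfg[["unaffected"]], cfg[["random"]])
        # fill the non-causal blocks of the four parental haplotypes
        other <- setdiff(seq_len(nb), a$blocks)
        fill <- function(rows) {
          R <- matrix(0L, nrow(rows), nb)
          R[, a$blocks] <- rows
          if (length(other)) R[, other] <- draw_hap_rows_at(pool, nrow(rows), other)
          R
        }
        list(FA1 = fill(a$FA1), FA2 = fill(a$FA2), MO1 = fill(a$MO1),
             MO2 = fill(a$MO2), tf = a$tf, tm = a$tm, status = a$status)
      })
      nf <- nrow(res$FA1)
      nsib <- ncol(res$status)
      ncon <- cfg[["affected"]] + cfg[["unaffected"]]
      fam_idx <- fam_counter + seq_len(nf)
      fam_rows[[length(fam_rows) + 1L]] <- data.frame(
        family_id = paste0("fam", fam_idx), config_label = cfg_name,
        replicate_id = r, stringsAsFactors = FALSE)
      if (nsib > 0L)
        sib_rows[[length(sib_rows) + 1L]] <- data.frame(
          fam = rep(fam_idx, each = nsib),
          sib = rep(seq_len(nsib), times = nf),
          tf = as.integer(t(res$tf)), tm = as.integer(t(res$tm)),
          status = as.integer(t(res$status)),
          constrained = rep(seq_len(nsib) <= ncon, times = nf),
          flag = "none", stringsAsFactors = FALSE)
      FA1[[length(FA1) + 1L]] <- res$FA1; FA2[[length(FA2) + 1L]] <- res$FA2
      MO1[[length(MO1) + 1L]] <- res$MO1; MO2[[length(MO2) + 1L]] <- res$MO2
      fam_counter <- fam_counter + nf
    }
  }
  new_ped_dataset(pool,
                  families = do.call(rbind, fam_rows),
                  FA1 = do.call(rbind, FA1), FA2 = do.call(rbind, FA2),
                  MO1 = do.call(rbind, MO1), MO2 = do.call(rbind, MO2),
                  sibs = if (length(sib_rows)) do.call(rbind, sib_rows) else
                    data.frame(fam = integer(0), sib = integer(0), tf = integer(0),
                               tm = integer(0), status = integer(0),
                               constrained = logical(0), flag = character(0)))
}

# Materialise one parental haplotype set (hap-row index matrix F x n_blocks)
# into an allele matrix F x M.
rows_to_haplotypes <- function(pool, rows) {
  M <- ncol(pool$haplotypes)
  H <- matrix(0L, nrow = nrow(rows), ncol = M)
  for (b in seq_along(pool$blocks)) {
    bc <- pool$blocks[[b]]
    H[, bc] <- pool$haplotypes[rows[, b], bc, drop = FALSE]
  }
  colnames(H) <- colnames(pool$haplotypes)
  H
}

#' Genotypes of every individual in a pedigree dataset
#'
#' @param ds a `ped_dataset`
#' @return list with `parents` (father/mother dosage matrices, one row per
#'   family) and `sibs` (dosage matrix aligned with `ds$sibs`)
#' @export
ped_genotypes <- function(ds) {
  fa1 <- rows_to_haplotypes(ds$pool, ds$FA1); fa2 <- rows_to_haplotypes(ds$pool, ds$FA2)
  mo1 <- rows_to_haplotypes(ds$pool, ds$MO1); mo2 <- rows_to_haplotypes(ds$pool, ds$MO2)
  s <- ds$sibs
  pick <- function(h1, h2, t, fam) {
    H <- h1[fam, , drop = FALSE]
    sw <- t == 2L
    H[sw, ] <- h2[fam[sw], , drop = FALSE]
    H
  }
  list(father = fa1 + fa2, mother = mo1 + mo2,
       sibs = pick(fa1, fa2, s$tf, s$fam) + pick(mo1, mo2, s$tm, s$fam))
}
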