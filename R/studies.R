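#' Marker sets of the two disease models
#'
#' The main-effect (ME) study simulates a 1,362-marker chromosome with one
#' main-effect SNP (RL0-855, per-allele target OR `exp(0.8) = 2.2255...`),
#' three auxiliary SNPs carrying only a weak interaction, and five
#' alternative single-SNP datasets used by the PM2 phenocopy mechanism. The
#' purely epistatic (EPI) study simulates a 401-marker chromosome with a
#' three-locus zero-main-effect penetrance table (target OR 4) and five
#' alternative three-locus tables.
#'
#' @return named list of marker-id sets
#' @export
me_loci <- function() {
  list(causal = "RL0-855",
       aux = c("RL0-75", "RL0-245", "RL0-457"),
       alt = c(alt1 = "RL0-179", alt2 = "RL0-111", alt3 = "RL0-210",
               alt4 = "RL0-503", alt5 = "RL0-995"))
}

#' @rdname me_loci
#' @export
epi_loci <- function() {
  list(causal = c("RL0-75", "RL0-153", "RL0-272"),
       alt = list(alt1 = c("RL0-66", "RL0-155", "RL0-268"),
                  alt2 = c("RL0-123", "RL0-79", "RL0-337"),
                  alt3 = c("RL0-63", "RL0-125", "RL0-332"),
                  alt4 = c("RL0-66", "RL0-116", "RL0-292"),
                  alt5 = c("RL0-63", "RL0-120", "RL0-329")))
}

#' Assemble the main-effect (ME) study
#'
#' Builds the chromosome, pins all disease-locus MAFs to a draw from
#' `[0.30, 0.45]` (common-variant regime), builds the haplotype pool, and
#' anchors every disease model's intercept to the target prevalence.
#'
#' @param n_markers chromosome size (default 1362)
#' @param pool_size haplotypes per block
#' @param ld_decay within-block LD persistence
#' @param beta main-effect log-odds per minor allele (default 0.8, i.e.
#'   OR 2.225540928)
#' @param aux_beta,gamma weak marginal effect and three-way interaction
#'   coefficient of the auxiliary SNPs
#' @param prevalence anchored population prevalence (default 0.10)
#' @param seed integer seed
#' @return a `study` list: `markers`, `pool`, `model`, `alt_models`,
#'   `causal`, `all_causal` (every locus modelled in main or alt models)
#' @export
me_study <- function(n_markers = 1362L, pool_size = 600L, ld_decay = 0.7,
                     beta = 0.8, aux_beta = 0.05, gamma = 0.3,
                     prevalence = 0.10, seed = 1L) {
  loci <- me_loci()
  mm <- build_marker_map(n_markers, seed = child_seed(seed, "me-map"))
  pin <- c(loci$causal, loci$aux, loci$alt)
  maf <- local_rng(child_seed(seed, "me-maf"),
                   stats::runif(length(pin), 0.30, 0.45))
  mm <- set_marker_maf(mm, pin, maf)
  pool <- build_haplotype_pool(mm, ld_decay = ld_decay, pool_size = pool_size,
                               seed = child_seed(seed, "me-pool"))
  main <- stats::setNames(c(beta, rep(aux_beta, 3L)), c(loci$causal, loci$aux))
  model <- logistic_disease_model(
    intercept = 0, main_effects = main,
    interactions = list(list(loci = loci$aux, gamma = gamma)))
  model <- anchor_prevalence(model, pool, prevalence)
  alt_models <- lapply(loci$alt, function(l) {
    m <- logistic_disease_model(0, stats::setNames(beta, l))
    anchor_prevalence(m, pool, prevalence)
  })
  structure(list(markers = mm, pool = pool, model = model,
                 alt_models = alt_models, causal = loci$causal,
                 all_causal = unique(c(loci$causal, loci$aux, loci$alt)),
                 name = "ME"),
            class = "study")
}

#' Assemble the purely epistatic (EPI) study
#'
#' Builds the chromosome and pool, then runs the genetic-algorithm
#' penetrance-table search once per model (main + five alternatives), each
#' at the pool's *empirical* allele frequencies of its loci so the
#' zero-marginal property holds exactly in the sampled population.
#'
#' @param n_markers chromosome size (default 401)
#' @param pool_size haplotypes per block
#' @param ld_decay within-block LD persistence
#' @param target_or target odds ratio of the high-risk class (default 4)
#' @param target_prevalence anchored table prevalence (default 0.10)
#' @param marginal_tolerance maximum marginal deviation (default 0.01)
#' @param ga_generations,ga_population GA budget
#' @param seed integer seed
#' @return a `study` list: `markers`, `pool`, `model` (a
#'   `penetrance_table`), `alt_models`, `causal`, `all_causal`
#' @export
epi_study <- function(n_markers = 401L, pool_size = 600L, ld_decay = 0.7,
                      target_or = 4, target_prevalence = 0.10,
                      marginal_tolerance = 0.01,
                      ga_generations = 400L, ga_population = 150L, seed = 1L) {
  loci <- epi_loci()
  mm <- build_marker_map(n_markers, seed = child_seed(seed, "epi-map"))
  pin <- unique(c(loci$causal, unlist(loci$alt, use.names = FALSE)))
  maf <- local_rng(child_seed(seed, "epi-maf"),
                   stats::runif(length(pin), 0.30, 0.45))
  mm <- set_marker_maf(mm, pin, maf)
  pool <- build_haplotype_pool(mm, ld_decay = ld_decay, pool_size = pool_size,
                               seed = child_seed(seed, "epi-pool"))
  freqs <- pool_allele_freq(pool)
  fit_table <- function(triple, tag) {
    cfg <- epistatic_search_config(
      target_or = target_or, maf = pmin(freqs[triple], 0.5), n_loci = 3L,
      population_size = ga_population, generations = ga_generations,
      marginal_tolerance = marginal_tolerance,
      target_prevalence = target_prevalence,
      seed = child_seed(seed, paste0("epi-ga-", tag)))
    generate_epistatic_table(cfg, loci = triple)
  }
  model <- fit_table(loci$causal, "main")
  alt_models <- Map(fit_table, loci$alt, names(loci$alt))
  structure(list(markers = mm, pool = pool, model = model,
                 alt_models = alt_models, causal = loci$causal,
                 all_causal = unique(c(loci$causal, unlist(loci$alt, use.names = FALSE))),
                 name = "EPI"),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("study %s: %d markers, causal %s\n", x$name, nrow(x$markers),
              paste(x$causal, collapse = "/")))
  invisible(x)
}
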