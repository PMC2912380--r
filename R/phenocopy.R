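#' Phenocopy injection specification
#'
#' Two mechanisms are supported. PM1 relabels population controls as
#' affected (the genomeSIMLA convention). PM2 substitutes cases with
#' affected individuals generated under alternative disease models whose
#' causal markers are disjoint from the main model's, so the phenocopies
#' are genuinely affected -- just by different genetic determinants.
#'
#' @param method `"PM1"` or `"PM2"`
#' @param level phenocopy fraction in `[0, 1)`; the study grid uses
#'   `{0, 0.05, 0.10, 0.20, 0.30, 0.45}`
#' @param alt_models for PM2, a named list of alternative disease models
#' @param seed integer seed
#' @return a `phenocopy_spec`
#' @export
phenocopy_spec <- function(method = c("PM1", "PM2"), level = 0,
                           alt_models = NULL, seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level >= 1)
    stop("level must lie in [0, 1)")
  if (method == "PM2" && level > 0 && (is.null(alt_models) || !length(alt_models)))
    stop("PM2 requires at least one alternative disease model")
  if (!is.null(alt_models) && is.null(names(alt_models)))
    names(alt_models) <- paste0("alt", seq_along(alt_models))
  s <- list(method = method, level = level, alt_models = alt_models,
            seed = as.integer(seed))
  class(s) <- "phenocopy_spec"
  s
}

# round(level * n) half away from zero (declared convention).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Inject PM1 phenocopies into a case-control dataset
#'
#' Replaces exactly `round(level * n_cases)` cases with population-control
#' genotype rows relabelled as affected (flag `"PM1"`). Controls and the
#' case count are untouched. With the same `seed` and reservoir, the
#' replaced-case set at a higher level is a superset of the set at a lower
#' level (common-random-numbers coupling across the phenocopy ladder).
#'
#' @param ds a `cc_dataset`
#' @param full_population_controls a `genotype_matrix` of fresh unaffected
#'   individuals (see [sample_population_controls()])
#' @param level phenocopy fraction in `[0, 1)`
#' @param seed integer seed
#' @return the modified `cc_dataset`
#' @export
pm1_case_control <- function(ds, full_population_controls, level, seed = 1L) {
  stopifnot(inherits(ds, "cc_dataset"))
  if (!is.numeric(level) || level < 0 || level >= 1) stop("level must lie in [0, 1)")
  if (level == 0) return(ds)
  res <- full_population_controls
  if (inherits(res, "genotype_matrix")) res <- res$genotypes
  cases <- which(ds$status == 1L)
  k <- as.integer(round_half_away(level * length(cases)))
  if (k == 0L) return(ds)
  if (nrow(res) < k)
    stop("population-control reservoir too small: need ", k, ", have ", nrow(res))
  local_rng(seed, {
    sel <- cases[sample.int(length(cases))][seq_len(k)]
    src <- sample.int(nrow(res))[seq_len(k)]
    ds$genotypes$genotypes[sel, ] <- res[src, , drop = FALSE]
    ds$phenocopy_flag[sel] <- "PM1"
    ds
  })
}

#' Inject PM1 phenocopies into a pedigree dataset
#'
#' Within selected families, one unaffected constrained sib is relabelled
#' affected (flagged `"PM1"`) and one affected constrained sib relabelled
#' unaffected, so every family keeps its configuration's affected/unaffected
#' design counts. The number of flagged sibs is `round(level * A)` where `A`
#' is the number of affected constrained sibs. Nested across levels under a
#' common seed.
#'
#' @param ds a `ped_dataset`
#' @param level phenocopy fraction in `[0, 1)`
#' @param seed integer seed
#' @return the modified `ped_dataset`
#' @export
pm1_pedigree <- function(ds, level, seed = 1L) {
  stopifnot(inherits(ds, "ped_dataset"))
  if (!is.numeric(level) || level < 0 || level >= 1) stop("level must lie in [0, 1)")
  if (level == 0) return(ds)
  s <- ds$sibs
  n_design_affected <- sum(s$status == 1L & s$constrained)
  k <- as.integer(round_half_away(level * n_design_affected))
  if (k == 0L) return(ds)
  local_rng(seed, {
    # per family, pair shuffled affected with shuffled unaffected constrained
    # sibs; each pair is one swap slot
    slots_aff <- integer(0); slots_unaff <- integer(0)
    for (f in seq_len(nrow(ds$families))) {
      aff <- which(s$fam == f & s$constrained & s$status == 1L)
      una <- which(s$fam == f & s$constrained & s$status == 0L)
      cap <- min(length(aff), length(una))
      if (cap > 0L) {
        aff <- aff[sample.int(length(aff))][seq_len(cap)]
        una <- una[sample.int(length(una))][seq_len(cap)]
        slots_aff <- c(slots_aff, aff)
        slots_unaff <- c(slots_unaff, una)
      }
    }
    if (length(slots_aff) < k)
      stop("phenocopy level ", level, " infeasible: only ", length(slots_aff),
           " swap slots for ", k, " phenocopies")
    ord <- sample.int(length(slots_aff))
    take <- ord[seq_len(k)]
    s$status[slots_aff[take]] <- 0L
    s$status[slots_unaff[take]] <- 1L
    s$flag[slots_unaff[take]] <- "PM1"
    ds$sibs <- s
    ds
  })
}

#' Inject PM2 phenocopies into a case-control dataset
#'
#' For each of `round(level * n_cases)` substitutions, an affected individual
#' is generated under a uniformly chosen alternative disease model and
#' replaces a distinct original case; the flag records the source model id.
#' Dataset size and case count are unchanged. Replacement is without
#' replacement on both sides, and the substituted-case set is nested across
#' levels under a common seed.
#'
#' @param ds a `cc_dataset`
#' @param spec a [phenocopy_spec()] with `method = "PM2"`
#' @param pool the `haplotype_pool` the dataset was sampled from
#' @return the modified `cc_dataset`
#' @export
pm2_case_control <- function(ds, spec, pool) {
  stopifnot(inherits(ds, "cc_dataset"), inherits(spec, "phenocopy_spec"),
            spec$method == "PM2")
  if (spec$level == 0) return(ds)
  if (is.null(spec$alt_models) || !length(spec$alt_models))
    stop("PM2 requires at least one alternative disease model")
  cases <- which(ds$status == 1L)
  k <- as.integer(round_half_away(spec$level * length(cases)))
  if (k == 0L) return(ds)
  # fixed permutation of cases and fixed per-position model assignment: the
  # level only decides how long a prefix is read, so levels nest
  perm <- local_rng(child_seed(spec$seed, "pm2-perm"),
                    cases[sample.int(length(cases))])
  assign_model <- local_rng(child_seed(spec$seed, "pm2-models"),
                            sample.int(length(spec$alt_models), length(cases),
                                       replace = TRUE))
  sel <- perm[seq_len(k)]
  msel <- assign_model[seq_len(k)]
  for (m in seq_along(spec$alt_models)) {
    pos <- which(msel == m)
    if (!length(pos)) next
    gen <- sample_case_control(pool, spec$alt_models[[m]], length(pos), 0L,
                               seed = child_seed(spec$seed, paste0("pm2-gen-", m)))
    ds$genotypes$genotypes[sel[pos], ] <- gen$genotypes$genotypes
    ds$phenocopy_flag[sel[pos]] <- paste0("PM2:", names(spec$alt_models)[m])
  }
  ds
}
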