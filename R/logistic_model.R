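#' Construct a mixed logistic disease model
#'
#' Disease susceptibility is modelled on the log-odds scale as
#' \deqn{\eta = \alpha + \sum_l \beta_l g_l + \sum_S \gamma_S \prod_{l \in S} g_l}
#' with `g` the minor-allele dosage (0/1/2), so a main-effect coefficient
#' `beta` implies a per-allele odds ratio `exp(beta)`. Interaction terms are
#' products of dosages.
#'
#' @param intercept baseline log-odds `alpha`
#' @param main_effects named numeric vector, marker id -> beta
#' @param interactions list of interaction terms; each element a list with
#'   `loci` (character vector of marker ids) and `gamma` (coefficient)
#' @return a `logistic_disease_model`
#' @export
logistic_disease_model <- function(intercept = 0, main_effects = numeric(0),
                                   interactions = list()) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(main_effects) && is.null(names(main_effects)))
    stop("main_effects must be named by marker id")
  for (it in interactions) {
    if (!is.list(it) || is.null(it$loci) || is.null(it$gamma))
      stop("each interaction needs $loci and $gamma")
  }
  m <- list(intercept = intercept, main_effects = main_effects,
            interactions = interactions)
  class(m) <- "logistic_disease_model"
  m
}

model_loci <- function(model) {
  UseMethod("model_loci")
}

#' @export
model_loci.logistic_disease_model <- function(model) {
  unique(c(names(model$main_effects),
           unlist(lapply(model$interactions, `[[`, "loci"), use.names = FALSE)))
}

#' Penetrance of genotypes under a logistic disease model
#'
#' @param model a `logistic_disease_model`
#' @param genotypes a named dosage vector, a dosage matrix with marker ids as
#'   column names, or a `genotype_matrix`
#' @return numeric vector of P(affected), one per genotype row, in (0, 1)
#' @examples
#' m <- logistic_disease_model(-2, c("RL0-855" = 0.8))
#' logistic_penetrance(m, c("RL0-855" = 2)) / logistic_penetrance(m, c("RL0-855" = 0))
#' @export
logistic_penetrance <- function(model, genotypes) {
  stopifnot(inherits(model, "logistic_disease_model"))
  G <- as_dosage_matrix(genotypes)
  need <- model_loci(model)
  missing <- setdiff(need, colnames(G))
  if (length(missing))
    stop("genotypes lack model marker(s): ", paste(missing, collapse = ", "))
  eta <- rep(model$intercept, nrow(G))
  for (l in names(model$main_effects))
    eta <- eta + model$main_effects[[l]] * G[, l]
  for (it in model$interactions) {
    prod_term <- rep(1, nrow(G))
    for (l in it$loci) prod_term <- prod_term * G[, l]
    eta <- eta + it$gamma * prod_term
  }
  unname(stats::plogis(eta))
}

as_dosage_matrix <- function(genotypes) {
  if (inherits(genotypes, "genotype_matrix")) return(genotypes$genotypes)
  if (is.matrix(genotypes)) return(genotypes)
  if (is.numeric(genotypes) && !is.null(names(genotypes)))
    return(matrix(genotypes, nrow = 1L, dimnames = list(NULL, names(genotypes))))
  stop("genotypes must be a genotype_matrix, a matrix, or a named vector")
}

#' Anchor the logistic intercept to a target population prevalence
#'
#' Solves for `alpha` so that the prevalence implied by the model under the
#' pool's exact multilocus genotype distribution equals `prevalence`
#' (1-D root finding; the multilocus law is enumerated block-exactly from the
#' weighted haplotype pool).
#'
#' @param model a `logistic_disease_model` (its intercept is ignored)
#' @param pool a `haplotype_pool` containing all model loci
#' @param prevalence target P(affected) in the population, default 0.10
#' @return the model with its intercept replaced by the anchored value
#' @export
anchor_prevalence <- function(model, pool, prevalence = 0.10) {
  stopifnot(inherits(model, "logistic_disease_model"),
            prevalence > 0, prevalence < 1)
  loci <- model_loci(model)
  joint <- locus_joint_distribution(pool, loci)
  G <- as.matrix(joint[, loci, drop = FALSE])
  w <- joint$prob
  f <- function(alpha) {
    m2 <- model
    m2$intercept <- alpha
    sum(w * logistic_penetrance(m2, G)) - prevalence
  }
  model$intercept <- stats::uniroot(f, c(-30, 10), tol = 1e-10)$root
  model
}

#' Assign affection status under a disease model
#'
#' Each individual is affected independently with probability equal to the
#' model's penetrance of their multilocus genotype.
#'
#' @param genotypes a `genotype_matrix` (or dosage matrix with marker-id
#'   column names) covering the model loci
#' @param model a `logistic_disease_model` or `penetrance_table`
#' @param seed integer seed
#' @return integer vector of 0/1 affection flags
#' @export
assign_status <- function(genotypes, model, seed = 1L) {
  p <- penetrance_of(model, genotypes)
  local_rng(seed, as.integer(stats::rbinom(length(p), 1L, p)))
}

penetrance_of <- function(model, genotypes) {
  if (inherits(model, "logistic_disease_model")) {
    logistic_penetrance(model, genotypes)
  } else if (inherits(model, "penetrance_table")) {
    table_penetrance(model, genotypes)
  } else {
    stop("unsupported disease model class: ", paste(class(model), collapse = "/"))
  }
}

#' @export
print.logistic_disease_model <- function(x, ...) {
  cat("logistic_disease_model\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  if (length(x$main_effects))
    cat("  main effects:",
        paste(sprintf("%s beta=%.3g (OR %.4f)", names(x$main_effects),
                      x$main_effects, exp(x$main_effects)), collapse = ", "), "\n")
  for (it in x$interactions)
    cat(sprintf("  interaction %s gamma=%.3g\n",
                paste(it$loci, collapse = "*"), it$gamma))
  invisible(x)
}
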