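#' Single-point association scan of a case-control dataset
#'
#' For every marker, computes the 1-df allelic chi-square on the 2x2 allele
#' count table and the Cochran-Armitage trend chi-square on the 2x3 genotype
#' table (scores 0/1/2), with no continuity correction, plus the allelic
#' odds ratio. Monomorphic markers get p = 1 and an undefined OR, flagged.
#'
#' @param ds a `cc_dataset` with at least one case and one control
#' @return an `assoc_result` data.frame with one row per marker: genotype
#'   counts in cases/controls, `chi2_allelic`, `p_allelic`, `neglog10p`,
#'   `or_allelic`, `chi2_trend`, `p_trend`, `monomorphic`
#' @export
single_point_scan <- function(ds) {
  stopifnot(inherits(ds, "cc_dataset"))
  G <- ds$genotypes$genotypes
  y <- ds$status
  if (!any(y == 1L) || !any(y == 0L)) stop("need at least one case and one control")
  gc_counts <- genotype_counts(G, y)
  with(gc_counts, {
    ncase <- r0 + r1 + r2
    nctrl <- s0 + s1 + s2
    a <- r1 + 2 * r2; b <- 2 * ncase - a        # case minor / major alleles
    c_ <- s1 + 2 * s2; d <- 2 * nctrl - c_      # control minor / major
    N <- a + b + c_ + d
    mono <- (a + c_) == 0 | (b + d) == 0
    chi2_a <- N * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    chi2_a[mono] <- 0
    p_a <- stats::pchisq(chi2_a, df = 1, lower.tail = FALSE)
    p_a[mono] <- 1
    or <- (a * d) / (b * c_)
    or[mono | b == 0 | c_ == 0] <- NA_real_
    # Cochran-Armitage trend test, scores w = (0, 1, 2)
    n1 <- r1 + s1; n2 <- r2 + s2
    Ntot <- ncase + nctrl
    Tw <- r1 + 2 * r2
    Sw <- n1 + 2 * n2
    Sw2 <- n1 + 4 * n2
    num <- (Ntot * Tw - ncase * Sw)^2 * Ntot
    den <- ncase * (Ntot - ncase) * (Ntot * Sw2 - Sw^2)
    chi2_t <- ifelse(den > 0, num / den, 0)
    p_t <- stats::pchisq(chi2_t, df = 1, lower.tail = FALSE)
    p_t[den <= 0] <- 1
    res <- data.frame(
      marker = colnames(G), index = ds$genotypes$markers$index,
      case_g0 = r0, case_g1 = r1, case_g2 = r2,
      ctrl_g0 = s0, ctrl_g1 = s1, ctrl_g2 = s2,
      chi2_allelic = chi2_a, p_allelic = p_a,
      neglog10p = -log10(p_a), or_allelic = or,
      chi2_trend = chi2_t, p_trend = p_t,
      monomorphic = mono, stringsAsFactors = FALSE)
    class(res) <- c("assoc_result", "data.frame")
    res
  })
}

# Per-marker genotype counts split by status; returns six count vectors.
genotype_counts <- function(G, y) {
  Gc <- G[y == 1L, , drop = FALSE]
  Gu <- G[y == 0L, , drop = FALSE]
  r1 <- colSums(Gc == 1L); r2 <- colSums(Gc == 2L); r0 <- nrow(Gc) - r1 - r2
  s1 <- colSums(Gu == 1L); s2 <- colSums(Gu == 2L); s0 <- nrow(Gu) - s1 - s2
  list(r0 = r0, r1 = r1, r2 = r2, s0 = s0, s1 = s1, s2 = s2)
}

#' Hardy-Weinberg equilibrium screen in controls
#'
#' 1-df chi-square of observed vs HWE-expected genotype counts among
#' controls (expected counts from the control allele frequency estimate).
#' A marker drifting out of HWE in controls is the signature of the false
#' positive the PM2 mechanism can create at a marker whose genotype mixture
#' differs between source datasets.
#'
#' @param ds a `cc_dataset` with controls present
#' @param alpha flagging threshold on the HWE p value (default 0.05)
#' @return an `hwe_result` data.frame: `chi2`, `p`, `flag` per marker
#' @export
hwe_scan <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "cc_dataset"))
  G <- ds$genotypes$genotypes
  y <- ds$status
  if (!any(y == 0L)) stop("no controls present")
  Gu <- G[y == 0L, , drop = FALSE]
  n1 <- colSums(Gu == 1L); n2 <- colSums(Gu == 2L); n0 <- nrow(Gu) - n1 - n2
  n <- nrow(Gu)
  phat <- (n1 + 2 * n2) / (2 * n)
  mono <- phat == 0 | phat == 1
  e0 <- n * (1 - phat)^2; e1 <- n * 2 * phat * (1 - phat); e2 <- n * phat^2
  chi2 <- ifelse(mono, 0,
                 (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  res <- data.frame(marker = colnames(G), chi2 = chi2, p = p,
                    flag = p < alpha, stringsAsFactors = FALSE)
  class(res) <- c("hwe_result", "data.frame")
  res
}

#' Transmission disequilibrium test over a pedigree dataset
#'
#' Counts transmitted (`b`) versus untransmitted (`c`) minor alleles from
#' heterozygous parents to all affected offspring, using the stored
#' transmission records, and reports the McNemar-type chi-square
#' `(b - c)^2 / (b + c)` per marker. Markers with no informative
#' transmissions are flagged and given p = 1.
#'
#' @param ds a `ped_dataset`
#' @return a `tdt_result` data.frame: `b`, `c`, `chi2`, `p`, `neglog10p`,
#'   `informative` per marker
#' @export
tdt_scan <- function(ds) {
  stopifnot(inherits(ds, "ped_dataset"))
  aff <- ds$sibs[ds$sibs$status == 1L, , drop = FALSE]
  if (nrow(aff) == 0L) stop("no affected offspring")
  fa1 <- rows_to_haplotypes(ds$pool, ds$FA1); fa2 <- rows_to_haplotypes(ds$pool, ds$FA2)
  mo1 <- rows_to_haplotypes(ds$pool, ds$MO1); mo2 <- rows_to_haplotypes(ds$pool, ds$MO2)
  count_parent <- function(h1, h2, t, fam) {
    H1 <- h1[fam, , drop = FALSE]; H2 <- h2[fam, , drop = FALSE]
    het <- H1 != H2
    tr <- H1
    swap <- t == 2L
    tr[swap, ] <- H2[swap, , drop = FALSE]
    b <- colSums(het & tr == 1L)
    c_ <- colSums(het & tr == 0L)
    list(b = b, c = c_)
  }
  pf <- count_parent(fa1, fa2, aff$tf, aff$fam)
  pm <- count_parent(mo1, mo2, aff$tm, aff$fam)
  b <- pf$b + pm$b
  c_ <- pf$c + pm$c
  informative <- (b + c_) > 0
  chi2 <- ifelse(informative, (b - c_)^2 / (b + c_), 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[!informative] <- 1
  res <- data.frame(marker = colnames(ds$pool$haplotypes),
                    b = b, c = c_, chi2 = chi2, p = p,
                    neglog10p = -log10(p), informative = informative,
                    stringsAsFactors = FALSE)
  class(res) <- c("tdt_result", "data.frame")
  res
}

#' Logistic regression with a three-way (k-way) interaction term
#'
#' Fits `status ~ g1 + ... + gk + g1:g2:...:gk` by maximum likelihood, with
#' dosage-coded main effects and the product of dosages as the interaction
#' term, and reports the Wald test of the product term. Used to verify that
#' a purely epistatic model carries a detectable interaction signal even
#' when no single-point test does.
#'
#' @param ds a `cc_dataset`
#' @param loci marker ids of the interacting loci
#' @return list with `coefficient`, `se`, `p_value` for the product term,
#'   `converged`, and `fit` (the `glm` object)
#' @export
logistic_interaction_test <- function(ds, loci) {
  stopifnot(inherits(ds, "cc_dataset"), length(loci) >= 2)
  G <- ds$genotypes$genotypes
  missing <- setdiff(loci, colnames(G))
  if (length(missing)) stop("unknown loci: ", paste(missing, collapse = ", "))
  df <- as.data.frame(G[, loci, drop = FALSE])
  names(df) <- paste0("g", seq_along(loci))
  df$product <- Reduce(`*`, df[paste0("g", seq_along(loci))])
  df$y <- ds$status
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  cf <- summary(fit)$coefficients
  out <- list(coefficient = cf["product", "Estimate"],
              se = cf["product", "Std. Error"],
              p_value = cf["product", "Pr(>|z|)"],
              converged = fit$converged,
              fit = fit)
  class(out) <- "interaction_test"
  out
}

#' @export
print.interaction_test <- function(x, ...) {
  cat(sprintf("logistic interaction term: coef %.4f (se %.4f), Wald p = %.3g%s\n",
              x$coefficient, x$se, x$p_value,
              if (x$converged) "" else " [did not converge]"))
  invisible(x)
}
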