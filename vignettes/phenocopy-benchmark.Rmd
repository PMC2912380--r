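---
title: "Simulating phenocopy effects on genetic association methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating phenocopy effects on genetic association methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenobench)
```

## The problem

A *phenocopy* is an individual labelled affected whose disease arises from
determinants other than the genetic model under study. In case-control and
family designs for complex traits, phenocopies are the norm rather than the
exception -- environmental causes, epigenetics, and genuinely heterogeneous
genetic architectures all put "cases" into the sample that carry none of the
risk genotypes being tested. phenobench simulates this situation end to end
and measures how much each standard analysis method loses as the phenocopy
fraction (PE level) climbs from 0% to 45%.

Two disease architectures are simulated:

* **Model ME** ("main effect"): a mixed logistic model on a 1,362-marker
  chromosome. One SNP (RL0-855) carries a per-allele log-odds
  $\beta = 0.80$, i.e. an allelic odds ratio $e^{0.80} = 2.2255$, and three
  auxiliary SNPs carry a very small marginal effect plus a three-way
  interaction. Penetrance is
  $P(D\mid g) = \mathrm{logit}^{-1}\!\big(\alpha + \sum_l \beta_l g_l +
  \sum_S \gamma_S \prod_{l\in S} g_l\big)$ with $g$ the minor-allele dosage.
* **Model EPI** ("purely epistatic"): a 27-cell penetrance table over three
  SNPs (RL0-75, RL0-153, RL0-272) on a 401-marker chromosome, constructed so
  that **no locus has a single-locus main effect** -- every single-locus
  marginal penetrance equals the prevalence -- while the odds of disease in
  the high-risk genotype class (cells above the table mean) versus the rest
  is a target value, 4 by default.

Phenocopies are injected by two mechanisms:

* **PM1** replaces a fraction of cases with population controls relabelled
  as affected (and, in pedigrees, swaps an unaffected sib to affected while
  demoting an affected sib, preserving each family's design counts).
* **PM2** replaces a fraction of cases with individuals who are *genuinely
  affected under a different disease model* -- five alternative models with
  disjoint causal loci -- which is the scenario where several genetic
  architectures produce one phenotype.

## The genotype simulator

Large-scale genotype data are emulated with a block-haplotype model rather
than a forward-time population simulation. The chromosome is partitioned
into LD blocks (5-15 markers by default); each block holds a pool of
haplotypes generated by a first-order latent-uniform copula chain: marker
$j$'s allele is the indicator $U_j < p_j$ where $U_j$ equals $U_{j-1}$ with
probability `ld_decay` and is refreshed otherwise. This keeps each marker's
minor allele frequency exactly at its target while giving within-block
$r^2$ that decays geometrically with distance; blocks are independent, so
across-block $r^2 \approx 0$. An individual is two independent haplotype
draws per block, which puts every marker in Hardy-Weinberg equilibrium at
the pool's frequencies. A trio's child receives one whole haplotype from
each parent, chosen uniformly, and the transmission record is kept for the
TDT.

What this emulates, and what it does not: the analyses under study depend
on LD-structured genotypes, HWE, Mendelian transmission, and the disease
models -- all reproduced here. It does **not** reproduce recombination-rate
realism, mutation, population growth, or any particular real LD landscape;
conclusions about those features cannot be drawn from these simulations.
Within-family transmissions are recombination-free, which is adequate for a
single chromosome of this length at the TDT's resolution.

Disease loci are pinned to MAFs drawn uniformly in $[0.30, 0.45]$ (the
"common variant, common disease" regime; the causal SNP's MAF must exceed
0.30).

## The epistatic table search

`generate_epistatic_table()` searches the 27-cell penetrance space with a
real-coded genetic algorithm (tournament selection, uniform crossover,
Gaussian mutation, elitism 2). Fitness is

$$-w_1\,\big|\log(\mathrm{OR}/\mathrm{OR}_\mathrm{target})\big|
  - w_2\,\max_{l,g}\big|m_{lg} - K\big|
  - w_3\,\big|K - K_\mathrm{target}\big|$$

where $m_{lg}$ is the HWE-weighted marginal penetrance of locus $l$ at
genotype $g$ and $K$ the prevalence, with defaults $w_1 = 1$, $w_2 = 10$,
$w_3 = 1$. Design choices worth recording:

* **Definition of the achieved OR.** The target odds ratio of a penetrance
  table is not uniquely defined; we use the odds of disease in the
  high-risk class (cells with penetrance above the HWE-weighted mean)
  versus the remaining cells. This is enumerable exactly over 27 cells and
  coincides with the high/low dichotomy MDR applies to the same cells --
  with balanced case-control sampling, MDR's cell threshold (case:control
  ratio 1) labels exactly the cells whose penetrance exceeds the
  prevalence, so the cross-validated MDR odds ratio estimates this quantity.
* **Prevalence anchoring.** OR and zero-marginal constraints leave the
  table's overall scale free; we anchor the prevalence at 0.10, the same
  value used to anchor the logistic model's intercept, as a credible
  complex-disease prevalence. This is the package's own choice (the third
  fitness term); the source material is silent on table scale.
* **Repair operator.** Offspring are, with probability 0.25, projected onto
  the linear subspace of zero-marginal tables (the marginal constraints are
  linear in the cells; the projector is precomputed from an SVD). This is a
  standard constraint-handling device and is why the search routinely
  reaches marginal deviations near machine precision rather than the 0.01
  tolerance.
* **Empirical frequencies.** Tables used inside a simulated study are
  fitted at the haplotype pool's empirical causal-locus frequencies, so the
  zero-marginal property holds exactly in the population actually sampled
  rather than at a nominal MAF.
* **Failure mode.** If the generation budget does not reach the marginal
  tolerance, a `phenobench_convergence_error` is signalled with the best
  table attached, rather than silently returning an unusable table.

```{r ga-demo}
cfg <- epistatic_search_config(target_or = 4, maf = 0.3, seed = 7)
tab <- generate_epistatic_table(cfg)
tab
round(table_marginals(tab)$marginals, 4)
```

## Cohorts, ascertainment and phenocopy injection

The pooled case-control design is 50 independent replicates of 200 cases +
200 controls (20,000 individuals), sampled by rejection against the
disease model with affected rows first; a draw cap of $10^6$ candidates
guards degenerate models. The pedigree design ascertains, per replicate, 25
families of each configuration -- 1 affected + 2 unaffected sibs, 3 + 1,
and 2 + 2 plus three "random" sibs whose status is drawn unconstrained --
for 50 × 25 × (5 + 6 + 9) = 25,000 individuals, parents included (the
stated total is only consistent if parents count). Parents' affection
status is left unknown; the TDT uses transmissions only.

Injection details that required a decision:

* `round(level × n)` phenocopies, rounded half away from zero.
* PM1's control reservoir is freshly drawn unaffected individuals, not the
  dataset's own controls, so no row is duplicated.
* PM1 in pedigrees is interpreted as a label swap (one unaffected
  constrained sib up, one affected constrained sib down) that preserves
  each family's design counts; the swapped-in sib is flagged. The original
  software's pedigree mechanics are documented only second-hand, so this
  interpretation is explicit. The "random extra" sibs are not swapped.
* PM2 substitutes without replacement on both sides and records the source
  model of every phenocopy in a provenance flag (emitted as a sidecar table
  next to PED files, which stay standard).
* **Common-random-numbers coupling.** Injectors draw a seeded permutation
  and read a prefix of length `round(level × n)`, so with one seed the
  substituted sets are nested along the PE ladder. Each level taken alone
  has exactly the specified distribution; the coupling only removes
  spurious cross-level Monte Carlo noise, which makes the monotone
  degradation visible at reduced problem sizes.

## Analysis methods

* Single-point scan: 1-df allelic chi-square and Cochran-Armitage trend
  chi-square (scores 0/1/2), no continuity correction, two-sided p from
  the chi-square distribution. Raw p values are reported; Bonferroni
  thresholds are applied only where a false-positive count needs one.
  Monomorphic markers get p = 1 and a flag.
* HWE screen in controls, 1-df chi-square against expected counts at the
  estimated allele frequency -- the diagnostic that catches PM2's
  characteristic false positive (a marker whose genotype mixture drifts
  out of equilibrium when cases from different source datasets are mixed).
* TDT: transmitted vs untransmitted minor alleles from heterozygous
  parents to affected offspring, $\chi^2 = (b-c)^2/(b+c)$, using the stored
  transmission records. Every affected sib contributes, so families with
  several affected sibs are over-weighted exactly as in a naive sib-TDT;
  this is accepted deliberately.
* Logistic interaction regression: `status ~ g1 + g2 + g3 + g1*g2*g3`
  (dosage products), Wald p for the product term.
* MDR: stratified 10-fold cross-validation; cells labelled high-risk on
  the training part iff case:control ratio ≥ the dataset-wide ratio (ties
  high); test individuals in training-empty cells are classified low-risk;
  predictions pooled over folds into one 2×2 table. Testing accuracy is
  **balanced** accuracy, (sensitivity + specificity)/2 -- the convention
  that reproduces the benchmark's reference tables exactly -- and the odds
  ratio gets a 95% Woolf (log-method) CI, with a Haldane-Anscombe 0.5
  correction (flagged) if a cell is empty. The random search samples
  combinations uniformly without replacement across 2- to 4-way sizes and
  falls back to exhaustive enumeration when the budget covers the space.

## Numerical and reproducibility choices

One master seed is expanded into per-stage child seeds
(`child_seed(seed, tag)`), so every stage -- map, pool, each replicate,
each injection, MDR folds, the GA -- is independently reproducible, and
all outputs are bit-identical under a fixed seed. Rejection batches have a
fixed size (512 candidates), which makes the accepted-case stream a stable
prefix in the quota; PM2's generation streams rely on this for cross-level
nesting. GA defaults (population 150, 400 generations, mutation rate 0.15,
sd 0.02) were chosen for reliable convergence of a 27-dimensional search
in about a second.

## What the tests show, and at what scale

The test suite exercises the full pipeline at reduced but representative
sizes, chosen so the suite runs in about a minute: the case-control
degradation ladders at 20 × (200+200) = 8,000 individuals, the pedigree
TDT ladder at 30 replicates = 15,000 individuals, and the forced-triple
MDR endpoints at the full 50 × (200+200) = 20,000 together with a
ten-seed trend check at a tenfold-reduced pool. The acceptance script runs
the EPI arm at full scale. Passing tests demonstrate the documented
properties of *these simulated populations* -- they do not certify
behaviour on real genotype data, whose LD structure, allele-frequency
spectrum and phenotyping error are richer than the generator's.

## Known limitations

* Absolute significance levels of the main-effect arm (e.g. the exact
  $-\log_{10} p$ at 0% PE) depend on coefficients of the original
  configuration that were never published; only the qualitative pattern --
  causal marker top-ranked throughout, monotone decline, epistatic loci
  invisible to single-point tests -- is reproducible, and that is what the
  package asserts.
* The purely epistatic tables are one member of a large family meeting the
  OR and zero-marginal constraints; quantities that depend on the *shape*
  of the table beyond its class odds ratio (for instance how much the MDR
  specificity shifts under heavy PM2 contamination) vary across admissible
  tables.
* No genomic control, covariates, missing genotypes, genotyping error or
  imputation; extended pedigrees are out of scope.
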