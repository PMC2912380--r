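#' Write a MAP file for a marker map
#'
#' Four columns: chromosome (1), marker id, genetic distance (0), base-pair
#' position (`index * 1000`).
#'
#' @param markers a `marker_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_map <- function(markers, path) {
  stopifnot(inherits(markers, "marker_map"))
  data.table::fwrite(data.table::data.table(
    chrom = 1L, id = markers$id, cm = 0L, bp = markers$index * 1000L),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

read_map <- function(path) {
  mp <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "id", "cm", "bp"))
  data.frame(id = mp$id, index = as.integer(mp$bp / 1000L),
             stringsAsFactors = FALSE)
}

# dosage (0/1/2 minor alleles) -> two-allele strings; allele 1 = major,
# allele 2 = minor
dosage_to_alleles <- function(G) {
  n <- nrow(G); M <- ncol(G)
  a1 <- matrix("1", n, M); a2 <- matrix("1", n, M)
  a2[G >= 1L] <- "2"
  a1[G == 2L] <- "2"
  out <- matrix("", n, 2L * M)
  out[, seq(1L, 2L * M, by = 2L)] <- a1
  out[, seq(2L, 2L * M, by = 2L)] <- a2
  out
}

#' Write a dataset as PED/MAP text files
#'
#' Standard 6 leading PED columns (family id, individual id, father id,
#' mother id, sex, phenotype with 1 = unaffected, 2 = affected, 0 = unknown)
#' followed by two allele columns per marker (1 = major, 2 = minor allele).
#' Case-control rows are written as singleton families with `0 0` parents;
#' pedigree datasets write parents (phenotype unknown) and sibs. Phenocopy
#' provenance is emitted as a sidecar table (`<ped_path>.phenocopies.tsv`)
#' so the PED file stays standard.
#'
#' @param ds a `cc_dataset` or `ped_dataset`
#' @param ped_path,map_path output paths
#' @return `ped_path`, invisibly
#' @export
write_ped_map <- function(ds, ped_path, map_path) {
  if (inherits(ds, "cc_dataset")) {
    G <- ds$genotypes$genotypes
    n <- nrow(G)
    ids <- ds$genotypes$individual_ids
    lead <- data.table::data.table(fam = ids, id = ids, father = "0", mother = "0",
                                   sex = 0L, pheno = ifelse(ds$status == 1L, 2L, 1L))
    al <- dosage_to_alleles(G)
    data.table::fwrite(cbind(lead, data.table::as.data.table(al)), ped_path,
                       sep = " ", col.names = FALSE)
    write_map(ds$genotypes$markers, map_path)
    prov <- data.frame(individual_id = ids, method = ds$phenocopy_flag,
                       stringsAsFactors = FALSE)
    data.table::fwrite(prov[prov$method != "none", , drop = FALSE],
                       paste0(ped_path, ".phenocopies.tsv"), sep = "\t")
  } else if (inherits(ds, "ped_dataset")) {
    g <- ped_genotypes(ds)
    fam <- ds$families$family_id
    rows <- list()
    rows[[1L]] <- cbind(data.table::data.table(
      fam = fam, id = paste0(fam, "_f"), father = "0", mother = "0",
      sex = 1L, pheno = 0L), data.table::as.data.table(dosage_to_alleles(g$father)))
    rows[[2L]] <- cbind(data.table::data.table(
      fam = fam, id = paste0(fam, "_m"), father = "0", mother = "0",
      sex = 2L, pheno = 0L), data.table::as.data.table(dosage_to_alleles(g$mother)))
    s <- ds$sibs
    sib_fam <- fam[s$fam]
    rows[[3L]] <- cbind(data.table::data.table(
      fam = sib_fam, id = paste0(sib_fam, "_s", s$sib),
      father = paste0(sib_fam, "_f"), mother = paste0(sib_fam, "_m"),
      sex = 0L, pheno = ifelse(s$status == 1L, 2L, 1L)),
      data.table::as.data.table(dosage_to_alleles(g$sibs)))
    tab <- data.table::rbindlist(rows)
    data.table::setkeyv(tab, "fam")
    data.table::fwrite(tab, ped_path, sep = " ", col.names = FALSE)
    write_map(ds$pool$markers, map_path)
    prov <- data.frame(individual_id = paste0(sib_fam, "_s", s$sib),
                       method = s$flag, stringsAsFactors = FALSE)
    data.table::fwrite(prov[prov$method != "none", , drop = FALSE],
                       paste0(ped_path, ".phenocopies.tsv"), sep = "\t")
  } else stop("unsupported dataset class")
  invisible(ped_path)
}

#' Read a PED/MAP pair
#'
#' Allele order within a genotype is treated as unordered (`1 2` and `2 1`
#' both read as dosage 1). Returns a `cc_dataset` when every row is a
#' founder singleton; otherwise a `ped_table` (data.frame of the six lead
#' columns plus the dosage matrix) -- transmission phase is not recoverable
#' from a PED file.
#'
#' @param ped_path,map_path input paths
#' @return a `cc_dataset` or a `ped_table`
#' @export
read_ped_map <- function(ped_path, map_path) {
  mp <- read_map(map_path)
  M <- nrow(mp)
  nf <- utils::count.fields(ped_path)
  bad_ln <- which(nf != 6L + 2L * M)
  if (length(bad_ln))
    stop("malformed PED: expected ", 6L + 2L * M, " fields, found ",
         nf[bad_ln[1L]], " (line ", bad_ln[1L], ")")
  pd <- data.table::fread(ped_path, header = FALSE, colClasses = "character")
  al <- as.matrix(pd[, -(1:6), with = FALSE])
  bad <- !(al %in% c("1", "2", "0"))
  if (any(bad)) {
    ln <- which(apply(bad, 1L, any))[1L]
    stop("malformed PED: unexpected allele code at line ", ln)
  }
  a1 <- al[, seq(1L, 2L * M, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * M, by = 2L), drop = FALSE]
  G <- (a1 == "2") + (a2 == "2")
  storage.mode(G) <- "integer"
  colnames(G) <- mp$id
  lead <- data.frame(fam = pd[[1L]], id = pd[[2L]], father = pd[[3L]],
                     mother = pd[[4L]], sex = as.integer(pd[[5L]]),
                     pheno = as.integer(pd[[6L]]), stringsAsFactors = FALSE)
  founders_only <- all(lead$father == "0" & lead$mother == "0") &&
    !anyDuplicated(lead$fam)
  if (founders_only) {
    mm <- data.frame(id = mp$id, index = mp$index, maf = NA_real_,
                     block_id = NA_integer_, stringsAsFactors = FALSE)
    class(mm) <- c("marker_map", "data.frame")
    status <- ifelse(lead$pheno == 2L, 1L, ifelse(lead$pheno == 1L, 0L, NA_integer_))
    return(new_cc_dataset(new_genotype_matrix(G, mm, ids = lead$id), status))
  }
  out <- list(info = lead, genotypes = G, markers = mp)
  class(out) <- "ped_table"
  out
}
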