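#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes as minor-allele dosages (0, 1, 2 or `NA`
#' for a missing call) for a set of individuals, together with per-SNP
#' metadata (identifier, chromosome, base-pair position, minor and major
#' allele).
#'
#' @param dosage Integer matrix, individuals in rows (rownames are
#'   individual ids), SNPs in columns (colnames are SNP ids). Values must
#'   be 0, 1, 2 or `NA`.
#' @param snps Data frame with columns `snp`, `chrom`, `bp`, `minor`,
#'   `major`; one row per column of `dosage`, in the same order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  if (!is.matrix(dosage)) stop_invalid("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop_invalid("`dosage` must carry individual and SNP ids as dimnames")
  req <- c("snp", "chrom", "bp", "minor", "major")
  if (!all(req %in% names(snps)))
    stop_invalid("`snps` must have columns %s", paste(req, collapse = ", "))
  if (nrow(snps) != ncol(dosage))
    stop_invalid("snp table rows (%d) != dosage columns (%d)",
                 nrow(snps), ncol(dosage))
  if (!identical(as.character(snps$snp), colnames(dosage)))
    stop_invalid("snp ids in `snps` must match dosage column names in order")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop_invalid("dosage values must be 0, 1, 2 or NA")
  if (any(snps$bp < 0)) stop_invalid("bp positions must be non-negative")
  storage.mode(dosage) <- "integer"
  rownames(snps) <- NULL
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param g A [genotype_matrix()].
#' @param individuals Character vector of individual ids (default: all).
#' @param snps Character vector of SNP ids (default: all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, individuals = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (!is.null(individuals)) {
    missing_ids <- setdiff(individuals, rownames(d))
    if (length(missing_ids))
      stop_invalid("unknown individual id(s): %s",
                   paste(utils::head(missing_ids, 5), collapse = ", "))
    d <- d[individuals, , drop = FALSE]
  }
  tab <- g$snps
  if (!is.null(snps)) {
    idx <- match(snps, tab$snp)
    if (anyNA(idx))
      stop_invalid("unknown SNP id(s): %s",
                   paste(utils::head(snps[is.na(idx)], 5), collapse = ", "))
    d <- d[, idx, drop = FALSE]
    tab <- tab[idx, , drop = FALSE]
  }
  genotype_matrix(d, tab)
}

#' Per-SNP minor-allele frequency
#'
#' Frequencies are computed over non-missing calls; optionally restricted
#' to a subset of individuals (e.g. unrelated controls plus one twin per
#' pair, so that duplicated monozygotic genomes do not bias estimates).
#'
#' @param g A [genotype_matrix()].
#' @param individuals Optional character vector restricting the estimation
#'   set.
#' @return Named numeric vector of allele frequencies of the recorded
#'   minor allele (may exceed 0.5 if orientation is stale; see
#'   [orient_minor()]).
#' @export
snp_maf <- function(g, individuals = NULL) {
  if (!is.null(individuals)) g <- subset_genotypes(g, individuals)
  d <- g$dosage
  n_called <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0] <- NA_real_
  stats::setNames(f, g$snps$snp)
}

#' Per-SNP call rate
#'
#' @param g A [genotype_matrix()].
#' @return Named numeric vector: fraction of individuals with a
#'   non-missing call at each SNP.
#' @export
snp_call_rate <- function(g) {
  stats::setNames(colMeans(!is.na(g$dosage)), g$snps$snp)
}

#' Re-orient alleles so the recorded minor allele is the less frequent one
#'
#' SNPs whose recorded minor-allele frequency exceeds 0.5 (in the
#' estimation set) have their dosages flipped (`2 - dosage`) and their
#' minor/major labels swapped.
#'
#' @inheritParams snp_maf
#' @return A re-oriented `genotype_matrix`.
#' @export
orient_minor <- function(g, individuals = NULL) {
  f <- snp_maf(g, individuals)
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) {
    g$dosage[, flip] <- 2L - g$dosage[, flip]
    tmp <- g$snps$minor[flip]
    g$snps$minor[flip] <- g$snps$major[flip]
    g$snps$major[flip] <- tmp
  }
  g
}

#' Write genotypes as PLINK text PED/MAP
#'
#' Writes `<prefix>.ped` (FamilyID, IndividualID, PaternalID, MaternalID,
#' Sex, Phenotype, then two allele columns per SNP; missing alleles coded
#' "0") and `<prefix>.map` (chromosome, SNP id, genetic distance 0,
#' bp position), plus a `<prefix>.snps.tsv` sidecar recording the
#' minor/major orientation so that a round trip through [read_plink()]
#' reproduces the dosage matrix exactly even when sample frequencies tie.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @param fam Optional data frame with columns `individual_id`, `family_id`,
#'   `phenotype` (1 = unaffected, 2 = affected, -9 = unknown). Defaults to
#'   one family per individual and phenotype -9.
#' @return Invisibly, the paths written.
#' @export
write_plink <- function(g, prefix, fam = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- rownames(g$dosage)
  if (is.null(fam)) {
    fam <- data.frame(individual_id = ids, family_id = ids,
                      phenotype = -9L, stringsAsFactors = FALSE)
  }
  fam <- fam[match(ids, fam$individual_id), ]
  n <- length(ids); m <- ncol(g$dosage)

  # allele pair per (individual, SNP): dosage d -> d minor alleles
  minor <- g$snps$minor; major <- g$snps$major
  d <- g$dosage
  a1 <- matrix(rep(major, each = n), n, m)
  a2 <- a1
  a1[d >= 1L & !is.na(d)] <- rep(minor, each = n)[d >= 1L & !is.na(d)]
  a2[d == 2L & !is.na(d)] <- rep(minor, each = n)[d == 2L & !is.na(d)]
  a1[is.na(d)] <- "0"; a2[is.na(d)] <- "0"
  geno <- matrix("", n, 2L * m)
  geno[, seq(1L, 2L * m, by = 2L)] <- a1
  geno[, seq(2L, 2L * m, by = 2L)] <- a2

  ped <- cbind(fam$family_id, ids, "0", "0", "0", fam$phenotype, geno)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  snp_path <- paste0(prefix, ".snps.tsv")
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chrom = g$snps$chrom, snp = g$snps$snp,
                    cm = 0, bp = g$snps$bp)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(g$snps, snp_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, snps = snp_path))
}

#' Read genotypes from PLINK text PED/MAP
#'
#' Alleles are counted against a minor/major orientation taken, in order of
#' preference, from the `alleles` argument, from a `<prefix>.snps.tsv`
#' sidecar written by [write_plink()], or inferred from sample allele
#' frequencies (less frequent allele = minor; ties broken alphabetically,
#' which is the only convention available when the PED carries no
#' orientation).
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @param alleles Optional data frame with columns `snp`, `minor`, `major`.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `fam` (the six leading PED columns as a data frame).
#' @export
read_plink <- function(prefix, alleles = NULL) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop_invalid("PED/MAP pair not found at prefix '%s'", prefix)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "snp", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  m <- nrow(map)
  fields <- scan(ped_path, what = "character", quiet = TRUE)
  ncol_ped <- 6L + 2L * m
  if (length(fields) %% ncol_ped != 0L)
    stop_invalid("PED field count is not a multiple of %d", ncol_ped)
  ped <- matrix(fields, ncol = ncol_ped, byrow = TRUE)
  fam <- data.frame(family_id = ped[, 1], individual_id = ped[, 2],
                    paternal_id = ped[, 3], maternal_id = ped[, 4],
                    sex = ped[, 5], phenotype = ped[, 6],
                    stringsAsFactors = FALSE)
  a1 <- ped[, 6L + seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- ped[, 6L + seq(2L, 2L * m, by = 2L), drop = FALSE]

  if (is.null(alleles)) {
    sidecar <- paste0(prefix, ".snps.tsv")
    if (file.exists(sidecar))
      alleles <- utils::read.table(sidecar, header = TRUE,
                                   colClasses = "character")
  }
  minor <- character(m); major <- character(m)
  if (!is.null(alleles)) {
    idx <- match(map$snp, alleles$snp)
    if (anyNA(idx)) stop_invalid("allele table missing SNP(s) present in MAP")
    minor <- as.character(alleles$minor[idx])
    major <- as.character(alleles$major[idx])
  } else {
    for (j in seq_len(m)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[obs != "0"]
      lev <- sort(unique(obs))
      if (length(lev) == 0L) { minor[j] <- "A"; major[j] <- "B"; next }
      if (length(lev) == 1L) { minor[j] <- "?"; major[j] <- lev; next }
      cnt <- table(factor(obs, levels = lev))
      # ties resolve to the alphabetically first allele as minor
      minor[j] <- lev[which.min(cnt)]
      major[j] <- setdiff(lev, minor[j])[1]
    }
  }
  dos <- (a1 == rep(minor, each = nrow(ped))) +
         (a2 == rep(minor, each = nrow(ped)))
  dos[a1 == "0" | a2 == "0"] <- NA
  dos <- matrix(as.integer(dos), nrow(ped), m,
                dimnames = list(fam$individual_id, map$snp))
  snps <- data.frame(snp = map$snp, chrom = map$chrom, bp = map$bp,
                     minor = minor, major = major, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dos, snps), fam = fam)
}
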