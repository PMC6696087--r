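#' Remove SNPs with low call rate
#'
#' @param g A [genotype_matrix()].
#' @param min_rate Minimum fraction of non-missing calls (default 0.95).
#' @return List `genotypes` (filtered), `removed` (SNP ids),
#'   `call_rate` (named vector over the input SNPs).
#' @export
call_rate_filter <- function(g, min_rate = 0.95) {
  if (min_rate <= 0 || min_rate > 1)
    stop_invalid("`min_rate` must lie in (0, 1]")
  cr <- snp_call_rate(g)
  removed <- names(cr)[cr < min_rate]
  keep <- setdiff(g$snps$snp, removed)
  list(genotypes = subset_genotypes(g, snps = keep), removed = removed,
       call_rate = cr)
}

#' Remove SNPs with low minor-allele frequency
#'
#' Alleles are re-oriented first so the recorded minor allele is the less
#' frequent one in the estimation set; monomorphic SNPs (MAF 0) are
#' removed and counted separately.
#'
#' @param g A [genotype_matrix()].
#' @param min_maf Minimum minor-allele frequency (inclusive).
#' @param individuals Optional estimation subset (see [snp_maf()]).
#' @return List `genotypes`, `removed`, `removed_monomorphic`, `maf`.
#' @export
maf_filter <- function(g, min_maf = 0.05, individuals = NULL) {
  g <- orient_minor(g, individuals)
  f <- snp_maf(g, individuals)
  mono <- names(f)[is.na(f) | f == 0]
  low <- setdiff(names(f)[!is.na(f) & f < min_maf], mono)
  keep <- setdiff(g$snps$snp, c(mono, low))
  list(genotypes = subset_genotypes(g, snps = keep), removed = low,
       removed_monomorphic = mono, maf = f)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the p^2 : 2pq : q^2 expectation at the observed allele
#' frequency. Monomorphic input (allele frequency 0 or 1) is untestable
#' and returns p = 1 with a flag, by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectors allowed): major
#'   homozygote, heterozygote, minor homozygote.
#' @return Data frame `chi2`, `p`, `monomorphic`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop_invalid("total genotype count must be positive")
  q <- (2 * n_aa + n_Aa) / (2 * n)   # minor-allele frequency
  p <- 1 - q
  mono <- q == 0 | q == 1
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  chi2 <- ifelse(mono, 0,
                 (n_AA - eAA)^2 / eAA + (n_Aa - eAa)^2 / eAa +
                 (n_aa - eaa)^2 / eaa)
  pval <- ifelse(mono, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = pval, monomorphic = mono)
}

hwe_from_genotypes <- function(g, individuals = NULL) {
  if (!is.null(individuals)) g <- subset_genotypes(g, individuals)
  d <- g$dosage
  n_aa <- colSums(d == 2L, na.rm = TRUE)
  n_Aa <- colSums(d == 1L, na.rm = TRUE)
  n_AA <- colSums(d == 0L, na.rm = TRUE)
  res <- hwe_test(n_AA, n_Aa, n_aa)
  res$snp <- g$snps$snp
  res
}

#' Estimation set for allele-frequency-based QC
#'
#' Unrelated controls plus one twin per pair: using both members of an MZ
#' pair would count the same genome twice and bias allele-frequency and
#' Hardy-Weinberg estimates.
#'
#' @param pedigree Pedigree data frame (`individual_id`, `pair_id`,
#'   `zygosity`).
#' @return Character vector of individual ids.
#' @export
qc_estimation_ids <- function(pedigree) {
  ctrl <- pedigree$individual_id[pedigree$zygosity == "control"]
  twins <- pedigree[!is.na(pedigree$pair_id), , drop = FALSE]
  first <- twins$individual_id[!duplicated(twins$pair_id)]
  c(ctrl, first)
}

#' Apply the marker quality-control cascade
#'
#' Filters run in fixed order — call rate, then minor-allele frequency
#' (with allele re-orientation), then Hardy-Weinberg equilibrium — and a
#' SNP is attributed to the first filter it fails. Frequency-based stages
#' use `freq_individuals` when given (see [qc_estimation_ids()]).
#'
#' @param g A [genotype_matrix()].
#' @param min_call_rate Minimum per-SNP call rate (default 0.95).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @param hwe_p Minimum Hardy-Weinberg p-value (default 0.001); SNPs with
#'   smaller p are removed.
#' @param freq_individuals Optional estimation subset for MAF/HWE.
#' @return List `genotypes` (survivors) and `report` (class `qc_report`):
#'   per-SNP table (`snp`, `call_rate`, `maf`, `hwe_p`, `removed_by`) and
#'   a `counts` summary.
#' @export
apply_qc <- function(g, min_call_rate = 0.95, min_maf = 0.05,
                     hwe_p = 0.001, freq_individuals = NULL) {
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 ||
      min_maf > 0.5 || hwe_p < 0 || hwe_p > 1)
    stop_invalid("QC thresholds out of range")
  all_snps <- g$snps$snp
  cr <- snp_call_rate(g)
  g <- orient_minor(g, freq_individuals)
  f <- snp_maf(g, freq_individuals)
  hw <- hwe_from_genotypes(g, freq_individuals)
  hwe_pvals <- stats::setNames(hw$p, hw$snp)

  removed_by <- rep(NA_character_, length(all_snps))
  names(removed_by) <- all_snps
  fail_cr <- cr < min_call_rate
  fail_maf <- is.na(f) | f < min_maf
  fail_hwe <- hwe_pvals < hwe_p
  removed_by[fail_hwe] <- "hwe"
  removed_by[fail_maf] <- "maf"
  removed_by[fail_cr] <- "call_rate"   # first-failure attribution wins

  keep <- all_snps[is.na(removed_by)]
  if (!length(keep))
    stop("no SNPs survive quality control; pipeline cannot proceed",
         call. = FALSE)
  report <- structure(list(
    table = data.frame(snp = all_snps, call_rate = unname(cr),
                       maf = unname(f), hwe_p = unname(hwe_pvals),
                       removed_by = unname(removed_by),
                       stringsAsFactors = FALSE),
    counts = c(input = length(all_snps),
               call_rate = sum(removed_by == "call_rate", na.rm = TRUE),
               maf = sum(removed_by == "maf", na.rm = TRUE),
               hwe = sum(removed_by == "hwe", na.rm = TRUE),
               surviving = length(keep)),
    thresholds = c(min_call_rate = min_call_rate, min_maf = min_maf,
                   hwe_p = hwe_p)), class = "qc_report")
  list(genotypes = subset_genotypes(g, snps = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  input: %d  removed: call-rate %d, MAF %d, HWE %d  surviving: %d\n",
              x$counts["input"], x$counts["call_rate"], x$counts["maf"],
              x$counts["hwe"], x$counts["surviving"]))
  invisible(x)
}
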