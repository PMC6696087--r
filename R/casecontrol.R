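#' Allele counts for a case-control contingency table
#'
#' Counts minor and major alleles contributed by cases and controls at one
#' SNP (two alleles per non-missing individual; missing genotypes
#' contribute none).
#'
#' @param g A [genotype_matrix()].
#' @param snp SNP id.
#' @param case_ids,control_ids Disjoint individual id sets.
#' @return List `a` (case minor), `b` (case major), `c` (control minor),
#'   `d` (control major), `maf_case`, `maf_control`.
#' @export
allele_counts <- function(g, snp, case_ids, control_ids) {
  if (length(intersect(case_ids, control_ids)))
    stop_invalid("case and control id sets overlap")
  j <- match(snp, g$snps$snp)
  if (is.na(j)) stop_invalid("unknown SNP '%s'", snp)
  dc <- g$dosage[case_ids, j]; du <- g$dosage[control_ids, j]
  a <- sum(dc, na.rm = TRUE); nc <- sum(!is.na(dc))
  c_ <- sum(du, na.rm = TRUE); nu <- sum(!is.na(du))
  list(a = a, b = 2 * nc - a, c = c_, d = 2 * nu - c_,
       maf_case = if (nc) a / (2 * nc) else NA_real_,
       maf_control = if (nu) c_ / (2 * nu) else NA_real_)
}

#' Basic allelic chi-square test
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2 x 2 table
#' of minor/major allele counts in cases versus controls, via the
#' closed form N (ad - bc)^2 / (r1 r2 c1 c2). An empty margin makes the
#' table untestable: p = 1 with a flag.
#'
#' @param a,b,c,d Allele counts (vectors allowed): case minor, case major,
#'   control minor, control major.
#' @return Data frame `chi2`, `p`, `untestable`.
#' @export
allelic_test <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop_invalid("allele counts must be >= 0")
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  bad <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  chi2 <- ifelse(bad, NA_real_, N * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  p <- ifelse(bad, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = p, untestable = bad)
}

#' Allelic odds ratio (minor versus major allele)
#'
#' OR = (a d) / (b c); values above 1 indicate minor-allele enrichment in
#' cases. Under the default Haldane-Anscombe correction 0.5 is added to
#' every cell if (and only if) any cell is zero, so the estimate is always
#' finite and positive; the test statistic is never corrected.
#'
#' @param a,b,c,d Allele counts (vectors allowed), as in [allelic_test()].
#' @param zero_cell `"haldane"` (default) or `"none"` (errors on a zero
#'   denominator).
#' @return Numeric odds ratio(s).
#' @export
odds_ratio <- function(a, b, c, d, zero_cell = c("haldane", "none")) {
  zero_cell <- match.arg(zero_cell)
  any0 <- a == 0 | b == 0 | c == 0 | d == 0
  if (zero_cell == "none") {
    if (any(b * c == 0))
      stop_invalid("zero denominator cell; use zero_cell = 'haldane'")
    return(a * d / (b * c))
  }
  h <- ifelse(any0, 0.5, 0)
  (a + h) * (d + h) / ((b + h) * (c + h))
}

#' Bonferroni adjustment
#'
#' @param p Numeric p-values in [0, 1].
#' @param m Number of tests in the family (default `length(p)`; must be at
#'   least that).
#' @return `min(1, p * m)` per value.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  if (m < length(p)) stop_invalid("`m` must be >= number of p-values")
  pmin(1, p * m)
}

#' Benjamini-Hochberg step-up adjusted p-values (q-values)
#'
#' Sorts the p-values ascending and takes q_(i) = min over j >= i of
#' p_(j) m / j, clamped to 1, restoring the original order. Output is
#' monotone in sorted-p order and never below the raw p.
#'
#' @param p Numeric p-values in [0, 1].
#' @return Numeric q-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(p[o] * (m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

cc_one_stratum <- function(g, snp_ids, case_ids, control_ids, m_tests) {
  rows <- lapply(snp_ids, function(s) {
    ct <- allele_counts(g, s, case_ids, control_ids)
    tst <- allelic_test(ct$a, ct$b, ct$c, ct$d)
    data.frame(snp = s, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               maf_case = ct$maf_case, maf_control = ct$maf_control,
               chi2 = tst$chi2, p = tst$p,
               odds_ratio = odds_ratio(ct$a, ct$b, ct$c, ct$d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p, m = m_tests)
  out$q_bh <- bh_adjust(out$p)
  out
}

#' Severity-stratified case-control association over trait QTNs
#'
#' Runs the allelic test separately for the Q1 (least severe) and Q4
#' (most severe) case strata against unrelated controls, restricted to the
#' screened QTN SNPs. Bonferroni and Benjamini-Hochberg corrections use
#' the QTN count within each stratum as the testing family. SNPs
#' significant (BH q <= `fdr`) in both strata enter the odds-ratio
#' contrast table.
#'
#' @param g A [genotype_matrix()].
#' @param qtns QTN table from [select_qtns()] (or any data frame with a
#'   `snp` column).
#' @param q1_ids,q4_ids Case ids per stratum (from [select_extremes()]).
#' @param control_ids Unrelated control ids.
#' @param fdr BH false-discovery-rate threshold (default 0.10).
#' @return List `results` (per stratum x SNP: counts, MAFs, chi2, p, OR,
#'   adjusted p, `significant`) and `contrasts` (per doubly-significant
#'   SNP: OR_Q1, OR_Q4, p_Q1, p_Q4, `direction` — "concordant" if both
#'   ORs sit on the same side of 1, else "discordant").
#' @export
run_stratified_cc <- function(g, qtns, q1_ids, q4_ids, control_ids,
                              fdr = 0.10) {
  if (!nrow(qtns)) stop_invalid("QTN set is empty")
  snp_ids <- qtns$snp
  strata <- list(Q1 = q1_ids, Q4 = q4_ids)
  res <- list()
  for (s in names(strata)) {
    ids <- strata[[s]]
    if (!length(ids)) {
      warning(sprintf("stratum %s is empty; skipped", s), call. = FALSE)
      next
    }
    r <- cc_one_stratum(g, snp_ids, ids, control_ids, length(snp_ids))
    r$stratum <- s
    r$significant <- r$q_bh <= fdr
    res[[s]] <- r
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  contrasts <- data.frame(snp = character(), OR_Q1 = numeric(),
                          OR_Q4 = numeric(), p_Q1 = numeric(),
                          p_Q4 = numeric(), direction = character(),
                          stringsAsFactors = FALSE)
  if (all(c("Q1", "Q4") %in% names(res))) {
    sig1 <- res$Q1[res$Q1$significant, "snp"]
    sig4 <- res$Q4[res$Q4$significant, "snp"]
    both <- intersect(sig1, sig4)
    if (length(both)) {
      i1 <- match(both, res$Q1$snp); i4 <- match(both, res$Q4$snp)
      or1 <- res$Q1$odds_ratio[i1]; or4 <- res$Q4$odds_ratio[i4]
      contrasts <- data.frame(
        snp = both, OR_Q1 = or1, OR_Q4 = or4,
        p_Q1 = res$Q1$p[i1], p_Q4 = res$Q4$p[i4],
        direction = ifelse((or1 - 1) * (or4 - 1) >= 0,
                           "concordant", "discordant"),
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, contrasts = contrasts)
}

#' Substitute the affected MZ co-twin's genotypes for the unaffected twin
#'
#' When only one member of an MZ pair was genotyped, the identical genome
#' justifies reusing the affected (dA.MZ) twin's genotype row for the
#' unaffected (dNA.MZ) co-twin. Pairs whose genotyped member is missing
#' from the matrix are excluded with a warning.
#'
#' @param g A [genotype_matrix()].
#' @param pair_map Data frame with columns `target_id` (individual to
#'   (re)genotype, e.g. the dNA.MZ twin) and `source_id` (the genotyped
#'   co-twin).
#' @return A `genotype_matrix` in which every target row is an exact copy
#'   of its source row (rows appended when the target was absent).
#' @export
substitute_mz_cotwin_genotypes <- function(g, pair_map) {
  if (!nrow(pair_map)) return(g)
  have <- pair_map$source_id %in% rownames(g$dosage)
  if (any(!have)) {
    warning(sprintf("%d pair(s) lack a genotyped co-twin; excluded",
                    sum(!have)), call. = FALSE)
    pair_map <- pair_map[have, , drop = FALSE]
  }
  if (!nrow(pair_map)) return(g)
  d <- g$dosage
  new <- !(pair_map$target_id %in% rownames(d))
  if (any(new)) {
    add <- d[pair_map$source_id[new], , drop = FALSE]
    rownames(add) <- pair_map$target_id[new]
    d <- rbind(d, add)
  }
  d[pair_map$target_id[!new], ] <- d[pair_map$source_id[!new], ]
  genotype_matrix(d, g$snps)
}

#' Discordant-DZ case versus co-twin association
#'
#' Exploratory genome-wide allelic association using the affected members
#' of discordant DZ pairs as cases and their unaffected co-twins as
#' controls. All supplied SNPs are eligible (no QTN restriction) and no
#' multiple-testing correction is applied; instead, results are filtered
#' to the nominal joint criterion p <= `p_cut` and odds ratio >= `or_cut`
#' (both inclusive).
#'
#' @param g A [genotype_matrix()].
#' @param case_ids Affected discordant-DZ twin ids.
#' @param control_ids Their unaffected co-twin ids.
#' @param p_cut Nominal p-value cut (default 0.05).
#' @param or_cut Odds-ratio cut (default 3.0).
#' @return Data frame of qualifying SNPs (`snp`, counts, MAFs, `chi2`,
#'   `p`, `odds_ratio`), with attributes `n_tested` (SNPs tested) and
#'   `n_nominal` (SNPs with p <= `p_cut` before the OR filter).
#' @export
dz_discordant_cc <- function(g, case_ids, control_ids, p_cut = 0.05,
                             or_cut = 3.0) {
  if (length(intersect(case_ids, control_ids)))
    stop_invalid("case and control id sets overlap")
  dc <- g$dosage[case_ids, , drop = FALSE]
  du <- g$dosage[control_ids, , drop = FALSE]
  a <- colSums(dc, na.rm = TRUE); nc <- colSums(!is.na(dc))
  cc <- colSums(du, na.rm = TRUE); nu <- colSums(!is.na(du))
  b <- 2 * nc - a; d <- 2 * nu - cc
  tst <- allelic_test(a, b, cc, d)
  or <- odds_ratio(a, b, cc, d)
  out <- data.frame(snp = g$snps$snp, a = a, b = b, c = cc, d = d,
                    maf_case = ifelse(nc > 0, a / (2 * nc), NA_real_),
                    maf_control = ifelse(nu > 0, cc / (2 * nu), NA_real_),
                    chi2 = tst$chi2, p = tst$p, odds_ratio = or,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  keep <- out[out$p <= p_cut & out$odds_ratio >= or_cut, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_tested") <- nrow(out)
  attr(keep, "n_nominal") <- sum(out$p <= p_cut)
  keep
}
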