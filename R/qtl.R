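#' Single-SNP quantitative trait regression
#'
#' Ordinary least-squares regression of a cumulative trait score on
#' minor-allele dosage (additive 0/1/2 coding). Individuals with a missing
#' dosage are dropped casewise; the Wald t statistic `beta/se` is referred
#' to a t distribution with n - 2 degrees of freedom (two-sided). A
#' constant dosage (or constant score) is untestable and returns
#' `beta = 0`, `p = 1` with a flag.
#'
#' @param dosage Numeric vector of dosages, `NA` allowed.
#' @param trait_score Numeric vector of scores, same length.
#' @return List `n`, `beta`, `se`, `t`, `p`, `maf`, `untestable`.
#' @export
qtl_regression <- function(dosage, trait_score) {
  if (length(dosage) != length(trait_score))
    stop_invalid("dosage and trait_score lengths differ")
  ok <- !is.na(dosage) & !is.na(trait_score)
  x <- dosage[ok]; y <- trait_score[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete observations, got %d", n)
  sxx <- sum((x - mean(x))^2)
  maf <- mean(x) / 2
  if (sxx == 0 || stats::var(y) == 0)
    return(list(n = n, beta = 0, se = NA_real_, t = NA_real_, p = 1,
                maf = maf, untestable = TRUE))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  sse <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- beta / se
  list(n = n, beta = beta, se = se, t = t,
       p = 2 * stats::pt(-abs(t), n - 2), maf = maf, untestable = FALSE)
}

#' Genome-wide quantitative trait scan
#'
#' Runs the dosage-on-score OLS of [qtl_regression()] at every SNP for the
#' individuals carrying a given trait score (optionally restricted to one
#' twin subgroup), vectorised across SNPs with per-SNP casewise deletion.
#' Results are ordered by (chromosome, position).
#'
#' @param g A (QC-filtered) [genotype_matrix()].
#' @param scores Trait-score table from [cumulative_trait_scores()] with
#'   an `individual_id` column.
#' @param trait Trait column to analyse.
#' @param subgroup Optional subgroup label; default uses all rows of
#'   `scores` that have genotypes.
#' @return Data frame `snp`, `chrom`, `bp`, `n`, `maf`, `beta`, `se`,
#'   `t`, `p`, `untestable`, with attributes `trait` and `subgroup`.
#' @export
run_qtl_scan <- function(g, scores, trait, subgroup = NULL) {
  if (!trait %in% names(scores)) stop_invalid("unknown trait '%s'", trait)
  if (!is.null(subgroup))
    scores <- scores[!is.na(scores$subgroup) &
                     scores$subgroup == subgroup, , drop = FALSE]
  ids <- intersect(scores$individual_id, rownames(g$dosage))
  if (!length(ids))
    stop("no individuals shared between genotypes and scores", call. = FALSE)
  y <- scores[[trait]][match(ids, scores$individual_id)]
  X <- g$dosage[ids, , drop = FALSE]
  storage.mode(X) <- "double"

  obs <- !is.na(X) & !is.na(y)      # y NA propagates row-wise
  Xz <- X; Xz[!obs] <- 0
  Yz <- matrix(y, nrow(X), ncol(X)); Yz[!obs] <- 0
  n <- colSums(obs)
  sx <- colSums(Xz); sy <- colSums(Yz)
  sxx <- colSums(Xz^2) - sx^2 / n
  syy <- colSums(Yz^2) - sy^2 / n
  sxy <- colSums(Xz * Yz) - sx * sy / n

  testable <- n >= 3 & sxx > 0 & syy > 0
  beta <- ifelse(testable, sxy / sxx, 0)
  sse <- pmax(syy - beta * sxy, 0)
  se <- ifelse(testable, sqrt(sse / (n - 2) / sxx), NA_real_)
  tstat <- ifelse(testable & se > 0, beta / se, NA_real_)
  p <- ifelse(testable & se > 0,
              2 * stats::pt(-abs(tstat), n - 2), 1)
  out <- data.frame(snp = g$snps$snp, chrom = g$snps$chrom, bp = g$snps$bp,
                    n = n, maf = sx / (2 * n), beta = beta, se = se,
                    t = tstat, p = p, untestable = !testable,
                    stringsAsFactors = FALSE)
  out <- out[order(suppressWarnings(as.integer(out$chrom)), out$chrom,
                   out$bp), ]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "subgroup") <- subgroup
  out
}

#' Select quantitative trait nucleotides from a scan
#'
#' Keeps SNPs whose unadjusted p-value is at or below the screening
#' threshold (default 1e-5, inclusive), ordered by ascending p with ties
#' broken by SNP id. An empty selection is returned with a warning.
#'
#' @param results Scan table from [run_qtl_scan()].
#' @param alpha Screening threshold on the raw p-value.
#' @return The qualifying rows, ordered by (p, snp), with attribute
#'   `alpha`.
#' @export
select_qtns <- function(results, alpha = 1e-5) {
  if (!nrow(results)) stop_invalid("empty result table")
  hits <- results[results$p <= alpha & !results$untestable, , drop = FALSE]
  hits <- hits[order(hits$p, hits$snp), , drop = FALSE]
  rownames(hits) <- NULL
  if (!nrow(hits))
    warning(sprintf("no SNP reaches the screening threshold p <= %g", alpha),
            call. = FALSE)
  attr(hits, "alpha") <- alpha
  attr(hits, "trait") <- attr(results, "trait")
  attr(hits, "subgroup") <- attr(results, "subgroup")
  hits
}
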