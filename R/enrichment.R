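#' Map SNPs to their nearest annotated gene
#'
#' A SNP falling inside a gene maps to that gene; otherwise it maps to the
#' gene with the nearest boundary on the same chromosome within
#' `max_distance`. Equidistant ties resolve to the lexicographically
#' smaller symbol, so the mapping is deterministic and independent of
#' input order. MAP positions are 1-based and converted internally to the
#' annotation's 0-based half-open intervals.
#'
#' @param snps Data frame `snp`, `chrom`, `bp` (1-based positions).
#' @param annotation Data frame `chrom`, `start`, `end`, `symbol`
#'   (0-based half-open; `start < end`).
#' @param max_distance Maximum gap, in bp, between a SNP and a gene
#'   boundary (default `Inf`, reproducing plain closest-gene semantics).
#' @return List `mapping` (data frame `snp`, `symbol`, `distance`; one
#'   row per mapped SNP) and `unmapped` (SNP ids with no eligible gene).
#' @export
map_snps_to_genes <- function(snps, annotation, max_distance = Inf) {
  if (any(annotation$start >= annotation$end))
    stop_invalid("annotation intervals must satisfy start < end")
  ann <- annotation[order(annotation$chrom, annotation$start,
                          annotation$symbol), , drop = FALSE]
  out <- vector("list", nrow(snps))
  unmapped <- character()
  for (i in seq_len(nrow(snps))) {
    pos <- snps$bp[i] - 1L   # 0-based
    cand <- ann[ann$chrom == snps$chrom[i], , drop = FALSE]
    if (!nrow(cand)) { unmapped <- c(unmapped, snps$snp[i]); next }
    dist <- ifelse(pos < cand$start, cand$start - pos,
                   ifelse(pos >= cand$end, pos - cand$end + 1L, 0L))
    dmin <- min(dist)
    if (dmin > max_distance) { unmapped <- c(unmapped, snps$snp[i]); next }
    sym <- sort(cand$symbol[dist == dmin])[1]
    out[[i]] <- data.frame(snp = snps$snp[i], symbol = sym,
                           distance = dmin, stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(mapping))
    mapping <- data.frame(snp = character(), symbol = character(),
                          distance = numeric(), stringsAsFactors = FALSE)
  rownames(mapping) <- NULL
  if (length(unmapped))
    warning(sprintf("%d SNP(s) could not be mapped to a gene",
                    length(unmapped)), call. = FALSE)
  list(mapping = mapping, unmapped = unmapped)
}

#' Upper-cumulative hypergeometric probability
#'
#' Probability of drawing at least `k` reference genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' belong to the reference set: the over-representation q-value
#' sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n), evaluated through the
#' numerically stable tail of [stats::phyper()].
#'
#' @param N Universe size.
#' @param K Reference genes in the universe.
#' @param n Query genes in the universe.
#' @param k Observed overlap.
#' @return Numeric probability in (0, 1]; vectorised over its arguments.
#' @export
hypergeometric_upper <- function(N, K, n, k) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(n, K)))
    stop_invalid("inconsistent hypergeometric counts (need 0 <= k <= min(n, K); K, n <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation test
#'
#' Upper-cumulative hypergeometric enrichment of a query gene set in a
#' reference risk-gene set within a stated gene universe. Symbols are
#' upper-cased and de-duplicated before intersection; query symbols
#' outside the universe are dropped with a warning and counted.
#'
#' @param query Character vector of query gene symbols.
#' @param reference Character vector of reference-set symbols.
#' @param universe Character vector defining the gene universe (e.g. all
#'   annotated genes). The universe choice materially affects q and must
#'   be stated with any reported result.
#' @param query_name,reference_name Labels carried into the result.
#' @return One-row data frame `query`, `reference`, `N`, `K`, `n`, `k`,
#'   `q`, `dropped` (query symbols outside the universe).
#' @export
enrich <- function(query, reference, universe, query_name = "query",
                   reference_name = "reference") {
  up <- function(x) unique(toupper(x))
  query <- up(query); reference <- up(reference); universe <- up(universe)
  outside <- setdiff(query, universe)
  if (length(outside))
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
  query <- intersect(query, universe)
  K <- length(intersect(reference, universe))
  n <- length(query)
  k <- length(intersect(query, reference))
  data.frame(query = query_name, reference = reference_name,
             N = length(universe), K = K, n = n, k = k,
             q = hypergeometric_upper(length(universe), K, n, k),
             dropped = length(outside), stringsAsFactors = FALSE)
}

#' Venn region counts for per-trait gene sets
#'
#' Exact counts of every exclusive intersection region among 2-5 named
#' gene sets, plus a pairwise disjointness indicator (used, e.g., to check
#' whether one trait's genes are disjoint from all others).
#'
#' @param sets Named list of 2-5 character vectors.
#' @return List `regions` (data frame `region` — set names joined by
#'   `&` — and `count`, exclusive of all non-member sets) and
#'   `pairwise_disjoint` (logical matrix).
#' @export
trait_set_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 5L)
    stop_invalid("`sets` must be a named list of 2-5 gene sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_invalid("all sets must be named")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  regions <- list()
  for (mask in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    members <- Reduce(intersect, sets[inset])
    if (any(!inset))
      members <- setdiff(members, Reduce(union, sets[!inset]))
    regions[[length(regions) + 1L]] <-
      data.frame(region = paste(nm[inset], collapse = "&"),
                 count = length(members), stringsAsFactors = FALSE)
  }
  pd <- matrix(NA, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pd[i, j] <- length(intersect(sets[[i]], sets[[j]])) == 0L
  list(regions = do.call(rbind, regions), pairwise_disjoint = pd)
}
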