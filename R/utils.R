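#' @keywords internal
"_PACKAGE"

#' The five behavioural traits scored by the workflow
#'
#' Trait names used throughout the package, in canonical order: spoken
#' language, nonverbal communication, play skills, social skills and
#' perseverative behaviours.
#'
#' @return Character vector of length 5.
#' @export
#' @examples
#' asd_traits()
asd_traits <- function() {
  c("spoken_language", "nonverbal_communication", "play_skills",
    "social_skills", "perseverative_behaviors")
}

# Deterministic sub-seed derivation: all randomness in the package flows
# from one master seed; each consumer gets its own stream index so stages
# stay reproducible independently of evaluation order.
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # linear congruential step keeps sub-seeds distinct, positive, < 2^31
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_fraction <- function(x, name, open_upper = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x > 0) &&
    all(if (open_upper) x < 1 else x <= 1)
  if (!ok) stop_invalid("`%s` must lie in (0, %s)", name,
                        if (open_upper) "1" else "1]")
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
      x != floor(x))
    stop_invalid("`%s` must be a positive integer count", name)
  invisible(as.integer(x))
}

#' Cohort bookkeeping: pair totals and genotyping coverage
#'
#' Sums per-subgroup twin-pair counts into zygosity and overall totals and
#' converts genotyped-pair counts into percentage coverage — the
#' arithmetic consistency checks run on a cohort's composition table.
#'
#' @param pair_counts Named numeric vector of pair counts per subgroup
#'   (names containing "MZ"/"DZ" are attributed to the respective
#'   zygosity).
#' @param genotyped_pairs Optional named numeric vector (`MZ`, `DZ`) of
#'   pairs with genome-wide genotypes.
#' @return List `total_pairs`, `mz_pairs`, `dz_pairs`, and (when coverage
#'   input is given) `coverage_pct` per zygosity (percentage scale, e.g.
#'   85.4).
#' @export
#' @examples
#' cohort_bookkeeping(c(cMZ = 88, dMZ = 25, cDZ = 56, dDZ = 115),
#'                    genotyped_pairs = c(MZ = 85, DZ = 146))
cohort_bookkeeping <- function(pair_counts, genotyped_pairs = NULL) {
  if (is.null(names(pair_counts)) || any(pair_counts < 0))
    stop_invalid("`pair_counts` must be a named vector of non-negative counts")
  mz <- sum(pair_counts[grepl("MZ", names(pair_counts))])
  dz <- sum(pair_counts[grepl("DZ", names(pair_counts))])
  out <- list(total_pairs = sum(pair_counts), mz_pairs = mz, dz_pairs = dz)
  if (!is.null(genotyped_pairs)) {
    denom <- c(MZ = mz, DZ = dz)[names(genotyped_pairs)]
    if (any(genotyped_pairs > denom, na.rm = TRUE))
      stop_invalid("genotyped pairs exceed pair totals")
    out$coverage_pct <- 100 * genotyped_pairs / denom
  }
  out
}
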