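#' Adjust raw interview item codes
#'
#' Raw ordinal item codes are cleaned for scoring: special administrative
#' codes (by default 6, 7, 8 and 9, used for "not applicable"/"unknown")
#' are recoded to 0, and remaining severity codes are capped at `cap`
#' (hyper-severity codes such as 4 collapse onto the cap). Output values
#' lie in `0..cap`.
#'
#' @param raw Data frame containing `item_*` columns of non-negative
#'   integer codes (extra columns pass through), or a bare numeric matrix.
#' @param cap Maximum retained severity (default 3).
#' @param special_codes Codes recoded to 0 before capping.
#' @return Object of the same shape with adjusted item scores.
#' @export
adjust_item_scores <- function(raw, cap = 3L, special_codes = c(6, 7, 8, 9)) {
  adjust <- function(x) {
    if (any(x < 0, na.rm = TRUE))
      stop_invalid("negative item codes are not valid")
    x[x %in% special_codes] <- 0L
    pmin(x, cap)
  }
  if (is.matrix(raw)) return(apply(raw, 2L, adjust))
  cols <- grep("^item_", names(raw), value = TRUE)
  if (!length(cols)) stop_invalid("no `item_*` columns found")
  raw[cols] <- lapply(raw[cols], adjust)
  raw
}

item_columns <- function(tab, trait_map) {
  missing_items <- setdiff(trait_map$item, names(tab))
  if (length(missing_items))
    stop_invalid("item(s) missing from table: %s",
                 paste(utils::head(missing_items, 5), collapse = ", "))
  invisible(TRUE)
}

#' Cumulative severity score per trait
#'
#' For each individual and trait, sums the adjusted scores of the items
#' mapped to that trait. The per-individual sum of the five trait scores
#' equals the sum of all item scores.
#'
#' @param adjusted Item table from [adjust_item_scores()] (data frame with
#'   `item_*` columns; id/label columns pass through).
#' @param trait_map Data frame `item`, `trait`.
#' @return Data frame: any of `individual_id`, `pair_id`, `zygosity`,
#'   `diagnosis`, `subgroup` present in the input, then one column per
#'   trait.
#' @export
cumulative_trait_scores <- function(adjusted, trait_map = default_trait_map()) {
  item_columns(adjusted, trait_map)
  keep <- intersect(c("individual_id", "pair_id", "zygosity",
                      "diagnosis", "subgroup"), names(adjusted))
  out <- adjusted[keep]
  for (tr in unique(trait_map$trait)) {
    its <- trait_map$item[trait_map$trait == tr]
    out[[tr]] <- as.integer(rowSums(adjusted[, its, drop = FALSE]))
  }
  out
}

#' Severity distribution profile for one trait and subgroup
#'
#' Sorts the subgroup's cumulative scores ascending and places individual
#' i of n at normalized rank 100 i / n, so subgroups of different sizes
#' share a common (0, 100] axis.
#'
#' @param scores Trait-score table from [cumulative_trait_scores()].
#' @param trait Trait column name.
#' @param subgroup Subgroup label to profile.
#' @return Data frame `rank` (in (0, 100]), `score` (non-decreasing).
#' @export
build_trait_profile <- function(scores, trait, subgroup) {
  if (!trait %in% names(scores)) stop_invalid("unknown trait '%s'", trait)
  x <- scores[[trait]][!is.na(scores$subgroup) & scores$subgroup == subgroup]
  if (!length(x)) stop_invalid("subgroup '%s' is empty", subgroup)
  x <- sort(x)
  data.frame(rank = 100 * seq_along(x) / length(x), score = x)
}

#' Quartile thresholds of a severity distribution
#'
#' Default convention is Tukey hinges (medians of the lower and upper
#' halves, each half including the overall median when n is odd), the
#' behaviour of common box-plot software; `linear_interpolation` uses
#' [stats::quantile()] type 7 instead.
#'
#' @param x Numeric vector of scores (n >= 4).
#' @param method `"tukey_hinge"` (default) or `"linear_interpolation"`.
#' @return List with `q1_threshold` (lower hinge / Q1) and `q4_threshold`
#'   (upper hinge / Q3, the entry bound of the top quartile).
#' @export
quartile_thresholds <- function(x, method = c("tukey_hinge",
                                              "linear_interpolation")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 4L)
    stop_invalid("need at least 4 observations for quartiles, got %d",
                 length(x))
  if (method == "tukey_hinge") {
    s <- sort(x); n <- length(s)
    half <- floor((n + 1) / 2)
    q1 <- stats::median(s[seq_len(half)])
    q3 <- stats::median(s[seq.int(n - half + 1L, n)])
  } else {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q1 <- q[1]; q3 <- q[2]
  }
  list(q1_threshold = q1, q4_threshold = q3)
}

#' Select severity-extreme individuals (first and fourth quartile)
#'
#' Cases in the Q1 stratum have scores less than or equal to the lower
#' quartile threshold; cases in Q4 have scores greater than or equal to
#' the upper threshold. Both comparisons are inclusive. With heavy ties an
#' individual can fall in both strata; such overlap is kept and warned
#' about.
#'
#' @param scores Trait-score table with an `individual_id` column.
#' @param trait Trait column name.
#' @param thresholds Output of [quartile_thresholds()] for the same
#'   subgroup and trait.
#' @param subgroup Optional subgroup label restricting the candidate set.
#' @return List `q1_ids`, `q4_ids` of individual ids.
#' @export
select_extremes <- function(scores, trait, thresholds, subgroup = NULL) {
  if (!is.null(subgroup))
    scores <- scores[!is.na(scores$subgroup) &
                     scores$subgroup == subgroup, , drop = FALSE]
  x <- scores[[trait]]
  q1 <- scores$individual_id[x <= thresholds$q1_threshold]
  q4 <- scores$individual_id[x >= thresholds$q4_threshold]
  overlap <- intersect(q1, q4)
  if (length(overlap))
    warning(sprintf("%d individual(s) fall in both Q1 and Q4 (tied scores)",
                    length(overlap)), call. = FALSE)
  list(q1_ids = q1, q4_ids = q4)
}

#' Two-sample t test for severity scores
#'
#' Student's pooled-variance t by default (Welch's unpooled variant by
#' flag), with a two-sided p-value. A degenerate comparison with zero
#' pooled variance returns `t = NA`, `p = 1` with a warning rather than
#' failing.
#'
#' @param a,b Numeric vectors, each with at least 2 observations.
#' @param equal_variance Use the pooled (Student) form; `FALSE` gives
#'   Welch's test with Satterthwaite degrees of freedom.
#' @return List `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, equal_variance = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop_invalid("each group needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (equal_variance) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  if (!is.finite(se) || se == 0) {
    warning("zero variance in both groups; test undefined, p set to 1",
            call. = FALSE)
    return(list(t = NA_real_, df = if (equal_variance) na + nb - 2 else NA_real_,
                p = 1, mean_a = mean(a), mean_b = mean(b)))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Compare two twin subgroups trait-by-trait and item-by-item
#'
#' Runs [two_sample_t()] on each of the five cumulative trait scores and
#' on each individual item, flagging comparisons with p <= `alpha`. No
#' multiple-testing correction is applied: the per-item screen reports raw
#' p-values.
#'
#' @param scores Trait-score table from [cumulative_trait_scores()].
#' @param items Adjusted item table (same individuals).
#' @param group_a,group_b Subgroup labels to compare.
#' @param trait_map Item-to-trait map.
#' @param alpha Significance threshold on the raw p-value.
#' @param equal_variance Passed to [two_sample_t()].
#' @return Data frame: `level` ("trait" or "item"), `name`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, `significant`.
#' @export
compare_subgroups <- function(scores, items, group_a, group_b,
                              trait_map = default_trait_map(),
                              alpha = 0.05, equal_variance = TRUE) {
  for (gl in c(group_a, group_b))
    if (!gl %in% scores$subgroup)
      stop_invalid("subgroup '%s' not present", gl)
  sel_a <- !is.na(scores$subgroup) & scores$subgroup == group_a
  sel_b <- !is.na(scores$subgroup) & scores$subgroup == group_b
  one <- function(level, name, xa, xb) {
    r <- suppressWarnings(two_sample_t(xa, xb, equal_variance))
    data.frame(level = level, name = name, mean_a = r$mean_a,
               mean_b = r$mean_b, t = r$t, df = r$df, p = r$p,
               significant = r$p <= alpha, stringsAsFactors = FALSE)
  }
  traits <- unique(trait_map$trait)
  rows <- lapply(traits, function(tr)
    one("trait", tr, scores[[tr]][sel_a], scores[[tr]][sel_b]))
  ia <- !is.na(items$subgroup) & items$subgroup == group_a
  ib <- !is.na(items$subgroup) & items$subgroup == group_b
  rows_i <- lapply(trait_map$item, function(it)
    one("item", it, items[[it]][ia], items[[it]][ib]))
  out <- do.call(rbind, c(rows, rows_i))
  rownames(out) <- NULL
  out
}
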