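#' Simulation configuration for a synthetic twin cohort
#'
#' Bundles and validates the parameters of the generative model: founder
#' genotypes in Hardy-Weinberg equilibrium, monozygotic (MZ) pairs with
#' identical genomes, dizygotic (DZ) pairs formed by Mendelian transmission
#' from two shared parents, additive trait liabilities with planted
#' quantitative trait nucleotides (QTNs), a pair-shared environment
#' component, ordinal item-score emission, and liability-threshold
#' diagnosis.
#'
#' @param n_mz_pairs,n_dz_pairs,n_controls,n_snps,n_qtns_per_trait Positive
#'   integer counts. Defaults mirror the cohort composition the workflow
#'   targets: 113 MZ pairs, 171 DZ pairs, 2438 unrelated controls.
#' @param maf_range Length-2 numeric in (0, 0.5]: founder minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param qtn_effect_sd Standard deviation of raw per-allele QTN effects
#'   (liability units) before rescaling to `h2_target`.
#' @param h2_target Narrow-sense heritability per trait in [0, 1).
#' @param c2_shared Pair-shared environment variance fraction per trait in
#'   [0, 1); `h2_target + c2_shared` must be < 1.
#' @param diagnosis_quantile Population quantile of mean liability above
#'   which an individual is diagnosed; in (0, 1).
#' @param item_noise_sd Standard deviation of the per-item normal noise
#'   added to the trait liability before thresholding into ordinal scores.
#' @param rng_seed Master seed; all stage-level streams are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mz_pairs = 113, n_dz_pairs = 171,
                       n_controls = 2438, n_snps = 2000,
                       n_qtns_per_trait = 3,
                       maf_range = c(0.05, 0.5), qtn_effect_sd = 1,
                       h2_target = 0.8, c2_shared = 0.1,
                       diagnosis_quantile = 0.75,
                       item_noise_sd = 0.5, rng_seed = 1L) {
  n_mz_pairs <- check_count(n_mz_pairs, "n_mz_pairs")
  n_dz_pairs <- check_count(n_dz_pairs, "n_dz_pairs")
  n_controls <- check_count(n_controls, "n_controls")
  n_snps <- check_count(n_snps, "n_snps")
  n_qtns_per_trait <- check_count(n_qtns_per_trait, "n_qtns_per_trait")
  if (length(maf_range) != 2L || any(maf_range <= 0) ||
      any(maf_range > 0.5) || maf_range[1] > maf_range[2])
    stop_invalid("`maf_range` must be an increasing pair within (0, 0.5]")
  h2 <- rep_len(h2_target, 5L); c2 <- rep_len(c2_shared, 5L)
  if (any(h2 < 0) || any(c2 < 0) || any(h2 + c2 >= 1))
    stop_invalid("per-trait h2_target + c2_shared must lie in [0, 1)")
  check_fraction(diagnosis_quantile, "diagnosis_quantile")
  if (item_noise_sd < 0) stop_invalid("`item_noise_sd` must be >= 0")
  if (5L * n_qtns_per_trait > n_snps)
    stop_invalid("not enough SNPs for %d QTNs per trait", n_qtns_per_trait)
  structure(list(n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
                 n_controls = n_controls, n_snps = n_snps,
                 n_qtns_per_trait = n_qtns_per_trait,
                 maf_range = as.numeric(maf_range),
                 qtn_effect_sd = qtn_effect_sd,
                 h2_target = h2, c2_shared = c2,
                 diagnosis_quantile = diagnosis_quantile,
                 item_noise_sd = item_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# synthetic marker map: SNPs spread over 22 autosomes at 10 kb spacing
make_snp_table <- function(n_snps, seed) {
  set.seed(seed)
  chrom <- sort(rep_len(1:22, n_snps))
  bp <- unlist(lapply(split(seq_len(n_snps), chrom), function(i)
    seq_along(i) * 10000L), use.names = FALSE)
  pairs <- cbind(sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
                 sample(c("A", "C", "G", "T"), n_snps, replace = TRUE))
  same <- pairs[, 1] == pairs[, 2]
  pairs[same, 2] <- c(A = "G", C = "T", G = "A", T = "C")[pairs[same, 1]]
  data.frame(snp = sprintf("rs%06d", seq_len(n_snps)),
             chrom = as.character(chrom), bp = bp,
             minor = pairs[, 1], major = pairs[, 2],
             stringsAsFactors = FALSE)
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP's minor-allele dosage is drawn independently per individual as
#' Binomial(2, maf); there is no missingness and no linkage disequilibrium.
#'
#' @param n_individuals Number of founders.
#' @param mafs Numeric vector of minor-allele frequencies, each in
#'   (0, 0.5].
#' @param seed Integer seed.
#' @param snps Optional SNP metadata table (as in [genotype_matrix()]);
#'   auto-generated when omitted.
#' @param ids Optional individual ids.
#' @return A [genotype_matrix()].
#' @export
simulate_founder_genotypes <- function(n_individuals, mafs, seed = 1L,
                                       snps = NULL, ids = NULL) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  if (any(mafs <= 0) || any(mafs > 0.5))
    stop_invalid("all `mafs` must lie in (0, 0.5]")
  m <- length(mafs)
  set.seed(seed)
  d <- matrix(stats::rbinom(n_individuals * m, 2L, rep(mafs, each = n_individuals)),
              n_individuals, m)
  if (is.null(ids)) ids <- sprintf("F%05d", seq_len(n_individuals))
  if (is.null(snps)) snps <- make_snp_table(m, seed)
  dimnames(d) <- list(ids, snps$snp)
  genotype_matrix(d, snps)
}

# transmitted minor-allele count from one parent: hap index h in {1,2},
# heterozygotes phased as hap1 = minor
transmit <- function(dosage, hap) {
  ifelse(dosage == 2L, 1L, ifelse(dosage == 0L, 0L, as.integer(hap == 1L)))
}

#' Simulate twin genotypes from founder parents
#'
#' Consumes two founders per pair (first the MZ pairs, then the DZ pairs,
#' in founder row order). An MZ pair is one Mendelian child duplicated;
#' a DZ pair is two independent Mendelian children of the same parents,
#' with the transmitted-haplotype indices recorded so realized
#' identity-by-descent (IBD) sharing is known per pair.
#'
#' @param founders A [genotype_matrix()] with at least
#'   `2 * (n_mz + n_dz)` individuals.
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param seed Integer seed.
#' @return List with `genotypes` (twins only; ids `<pair>_1`, `<pair>_2`)
#'   and `pairs` (data frame: `pair_id`, `id1`, `id2`, `zygosity`, and
#'   realized mean `ibd` sharing across SNPs).
#' @export
simulate_twin_genotypes <- function(founders, n_mz, n_dz, seed = 1L) {
  stopifnot(inherits(founders, "genotype_matrix"))
  if (n_mz < 0 || n_dz < 0 || n_mz + n_dz < 1)
    stop_invalid("need at least one twin pair")
  need <- 2L * (n_mz + n_dz)
  if (nrow(founders$dosage) < need)
    stop_invalid("need %d founders (two per pair), got %d",
                 need, nrow(founders$dosage))
  set.seed(seed)
  m <- ncol(founders$dosage)
  n_pairs <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  pair_id <- sprintf("%s%04d", zyg, c(seq_len(n_mz),
                                      if (n_dz) seq_len(n_dz) else integer()))
  d <- matrix(0L, 2L * n_pairs, m)
  ibd <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    pat <- founders$dosage[2L * k - 1L, ]
    mat <- founders$dosage[2L * k, ]
    if (zyg[k] == "MZ") {
      child <- transmit(pat, sample(1:2, m, TRUE)) +
               transmit(mat, sample(1:2, m, TRUE))
      d[2L * k - 1L, ] <- child
      d[2L * k, ] <- child
      ibd[k] <- 1
    } else {
      h1p <- sample(1:2, m, TRUE); h1m <- sample(1:2, m, TRUE)
      h2p <- sample(1:2, m, TRUE); h2m <- sample(1:2, m, TRUE)
      d[2L * k - 1L, ] <- transmit(pat, h1p) + transmit(mat, h1m)
      d[2L * k, ] <- transmit(pat, h2p) + transmit(mat, h2m)
      ibd[k] <- mean((h1p == h2p) + (h1m == h2m)) / 2
    }
  }
  ids <- as.vector(rbind(paste0(pair_id, "_1"), paste0(pair_id, "_2")))
  dimnames(d) <- list(ids, founders$snps$snp)
  list(genotypes = genotype_matrix(d, founders$snps),
       pairs = data.frame(pair_id = pair_id, id1 = paste0(pair_id, "_1"),
                          id2 = paste0(pair_id, "_2"), zygosity = zyg,
                          ibd = ibd, stringsAsFactors = FALSE))
}

#' Simulate additive trait liabilities
#'
#' For each of the five traits, liability = scaled additive genetic value
#' (planted QTN dosages times effects, empirically rescaled so the genetic
#' variance fraction equals `h2`) + a pair-shared normal term with variance
#' `c2` + an individual normal residual with variance `1 - h2 - c2`.
#' Liabilities are therefore standardized (mean 0, variance 1) at the
#' population level up to sampling error.
#'
#' @param genotypes A [genotype_matrix()] covering all individuals.
#' @param qtn_truth Data frame with columns `snp`, `trait`, `effect`
#'   (may be empty when `h2 = 0`).
#' @param h2,c2 Per-trait variance fractions, scalars or length-5 vectors;
#'   `h2 + c2 < 1`.
#' @param pair_ids Character vector, one per individual; unrelated
#'   individuals must carry unique ids so the shared term is private.
#' @param seed Integer seed.
#' @return Numeric matrix individuals x 5 traits, with dimnames.
#' @export
simulate_trait_liabilities <- function(genotypes, qtn_truth, h2, c2,
                                       pair_ids, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  traits <- asd_traits()
  h2 <- rep_len(h2, 5L); c2 <- rep_len(c2, 5L)
  if (any(h2 < 0) || any(c2 < 0) || any(h2 + c2 >= 1))
    stop_invalid("per-trait h2 + c2 must lie in [0, 1)")
  n <- nrow(genotypes$dosage)
  if (length(pair_ids) != n)
    stop_invalid("`pair_ids` must have one entry per individual")
  set.seed(seed)
  upair <- unique(pair_ids)
  liab <- matrix(0, n, 5L,
                 dimnames = list(rownames(genotypes$dosage), traits))
  for (t in seq_along(traits)) {
    qt <- qtn_truth[qtn_truth$trait == traits[t], , drop = FALSE]
    gval <- numeric(n)
    if (h2[t] > 0) {
      if (nrow(qt) == 0L)
        stop_invalid("h2 > 0 for trait '%s' but no QTNs planted", traits[t])
      X <- genotypes$dosage[, match(qt$snp, genotypes$snps$snp), drop = FALSE]
      X <- scale(X, center = TRUE, scale = FALSE)
      gval <- drop(X %*% qt$effect)
      v <- stats::var(gval)
      if (v <= 0)
        stop_invalid("planted QTNs for trait '%s' are monomorphic", traits[t])
      gval <- gval * sqrt(h2[t] / v)
      gval <- gval - mean(gval)
    }
    shared <- stats::rnorm(length(upair), 0, sqrt(c2[t]))[match(pair_ids, upair)]
    resid <- stats::rnorm(n, 0, sqrt(1 - h2[t] - c2[t]))
    liab[, t] <- gval + shared + resid
  }
  liab
}

#' Emit ordinal item scores from trait liabilities
#'
#' Each interview item belongs to one trait; its ordinal score in
#' 0..3 is the number of item cut points lying below the individual's
#' trait liability plus independent per-item normal noise. With zero noise
#' the item (and hence cumulative trait) score is non-decreasing in the
#' liability.
#'
#' @param liabilities Individuals x 5 matrix from
#'   [simulate_trait_liabilities()].
#' @param trait_map Data frame `item`, `trait` (see [default_trait_map()]).
#' @param cut_points Either a strictly increasing length-3 numeric vector
#'   used for every item, or an items x 3 matrix of per-item cut points.
#' @param noise_sd Standard deviation of the per-item noise (>= 0).
#' @param seed Integer seed.
#' @return Integer matrix individuals x items (columns named as in
#'   `trait_map$item`).
#' @export
liabilities_to_item_scores <- function(liabilities, trait_map,
                                       cut_points = c(-1, 0, 1),
                                       noise_sd = 0.5, seed = 1L) {
  n_items <- nrow(trait_map)
  if (is.vector(cut_points)) {
    if (length(cut_points) != 3L)
      stop_invalid("`cut_points` vector must have length 3")
    cut_points <- matrix(cut_points, n_items, 3L, byrow = TRUE)
  }
  if (nrow(cut_points) != n_items || ncol(cut_points) != 3L)
    stop_invalid("`cut_points` must be items x 3")
  if (any(cut_points[, 1] >= cut_points[, 2]) ||
      any(cut_points[, 2] >= cut_points[, 3]))
    stop_invalid("cut points must be strictly increasing per item")
  bad <- setdiff(trait_map$trait, asd_traits())
  if (length(bad)) stop_invalid("unknown trait(s): %s", paste(bad, collapse = ", "))
  set.seed(seed)
  n <- nrow(liabilities)
  scores <- matrix(0L, n, n_items,
                   dimnames = list(rownames(liabilities), trait_map$item))
  for (j in seq_len(n_items)) {
    x <- liabilities[, trait_map$trait[j]]
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    scores[, j] <- (x > cut_points[j, 1]) + (x > cut_points[j, 2]) +
                   (x > cut_points[j, 3])
  }
  scores
}

#' Assign liability-threshold diagnoses and twin subgroup labels
#'
#' Diagnosis: mean of the five trait liabilities exceeds the population
#' quantile threshold. Subgroup labels follow zygosity and pair-level
#' concordance: `cMZ`/`cDZ` for concordant affected pairs, `dA.MZ`/`dA.DZ`
#' for the affected and `dNA.MZ`/`dNA.DZ` for the unaffected member of a
#' discordant pair. Both-unaffected pairs and unrelated individuals get
#' `NA` (they remain available as control candidates).
#'
#' @param liabilities Individuals x 5 liability matrix.
#' @param diagnosis_quantile Quantile of mean liability in (0, 1) defining
#'   the threshold.
#' @param zygosity Character vector per individual: "MZ", "DZ" or
#'   "control".
#' @param pair_ids Character vector per individual; `NA` for unrelated
#'   individuals.
#' @return List: `diagnosis` (logical), `subgroup` (character, `NA` where
#'   unlabeled), `threshold` (numeric).
#' @export
assign_diagnosis_and_subgroups <- function(liabilities, diagnosis_quantile,
                                           zygosity, pair_ids) {
  check_fraction(diagnosis_quantile, "diagnosis_quantile")
  mean_liab <- rowMeans(liabilities)
  thr <- stats::quantile(mean_liab, diagnosis_quantile, names = FALSE)
  dx <- mean_liab > thr
  n <- length(dx)
  if (length(zygosity) != n || length(pair_ids) != n)
    stop_invalid("zygosity/pair_ids must have one entry per individual")
  sub <- rep(NA_character_, n)
  twin <- zygosity %in% c("MZ", "DZ") & !is.na(pair_ids)
  for (p in unique(pair_ids[twin])) {
    idx <- which(pair_ids == p & twin)
    if (length(idx) != 2L) next
    z <- zygosity[idx[1]]
    if (all(dx[idx])) {
      sub[idx] <- paste0("c", z)
    } else if (any(dx[idx])) {
      sub[idx[dx[idx]]] <- paste0("dA.", z)
      sub[idx[!dx[idx]]] <- paste0("dNA.", z)
    }
  }
  list(diagnosis = dx, subgroup = sub, threshold = thr)
}

#' Default item-to-trait map
#'
#' A synthetic allocation of the 88 interview items to the five traits
#' (20, 18, 15, 20 and 15 items respectively). The instrument's true
#' item composition per trait is not public, so this map is a documented
#' reconstruction; any two-column (`item`, `trait`) table may be supplied
#' in its place.
#'
#' @return Data frame with columns `item` (`item_01` .. `item_88`) and
#'   `trait`.
#' @export
default_trait_map <- function() {
  counts <- c(spoken_language = 20L, nonverbal_communication = 18L,
              play_skills = 15L, social_skills = 20L,
              perseverative_behaviors = 15L)
  data.frame(item = sprintf("item_%02d", 1:88),
             trait = rep(names(counts), counts),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic twin cohort
#'
#' Runs the full generative model under a [sim_config()]: founder and twin
#' genotypes, planted QTN effects, trait liabilities, ordinal item scores,
#' liability-threshold diagnosis and subgroup labels. All randomness is
#' derived from the config's master seed via fixed stream splitting.
#'
#' @param config A [sim_config()].
#' @param trait_map Item-to-trait map; defaults to [default_trait_map()].
#' @return An object of class `twin_cohort`: list with `genotypes`,
#'   `pedigree` (individual_id, pair_id, zygosity, diagnosis, subgroup),
#'   `liabilities`, `item_scores` (data frame: pedigree columns + item
#'   columns), `qtn_truth`, `pairs`, `diagnosis_threshold`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            trait_map = default_trait_map()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- split_seed(config$rng_seed, 8L)
  set.seed(seeds[1])
  mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  snps <- make_snp_table(config$n_snps, seeds[2])

  n_pairs <- config$n_mz_pairs + config$n_dz_pairs
  founders <- simulate_founder_genotypes(2L * n_pairs, mafs,
                                         seed = seeds[3], snps = snps)
  tw <- simulate_twin_genotypes(founders, config$n_mz_pairs,
                                config$n_dz_pairs, seed = seeds[4])
  ctrl <- simulate_founder_genotypes(config$n_controls, mafs,
                                     seed = seeds[5], snps = snps,
                                     ids = sprintf("C%05d",
                                                   seq_len(config$n_controls)))
  dosage <- rbind(tw$genotypes$dosage, ctrl$dosage)
  genotypes <- genotype_matrix(dosage, snps)

  pair_ids <- c(rep(tw$pairs$pair_id, each = 2L), rownames(ctrl$dosage))
  zygosity <- c(rep(tw$pairs$zygosity, each = 2L),
                rep("control", config$n_controls))

  set.seed(seeds[6])
  traits <- asd_traits()
  qtn_snps <- sample(snps$snp, 5L * config$n_qtns_per_trait)
  qtn_truth <- data.frame(
    snp = qtn_snps,
    trait = rep(traits, each = config$n_qtns_per_trait),
    effect = stats::rnorm(length(qtn_snps), 0, config$qtn_effect_sd),
    stringsAsFactors = FALSE)

  liab <- simulate_trait_liabilities(genotypes, qtn_truth,
                                     config$h2_target, config$c2_shared,
                                     pair_ids, seed = seeds[7])
  dxsub <- assign_diagnosis_and_subgroups(liab, config$diagnosis_quantile,
                                          zygosity, pair_ids)
  items <- liabilities_to_item_scores(liab, trait_map,
                                      noise_sd = config$item_noise_sd,
                                      seed = seeds[8])
  pedigree <- data.frame(individual_id = rownames(dosage),
                         pair_id = ifelse(zygosity == "control",
                                          NA_character_, pair_ids),
                         zygosity = zygosity,
                         diagnosis = dxsub$diagnosis,
                         subgroup = dxsub$subgroup,
                         stringsAsFactors = FALSE)
  item_scores <- cbind(pedigree, as.data.frame(items))
  rownames(item_scores) <- NULL
  structure(list(genotypes = genotypes, pedigree = pedigree,
                 liabilities = liab, item_scores = item_scores,
                 qtn_truth = qtn_truth, pairs = tw$pairs,
                 diagnosis_threshold = dxsub$threshold,
                 trait_map = trait_map, config = config),
            class = "twin_cohort")
}

#' @export
print.twin_cohort <- function(x, ...) {
  tab <- table(factor(x$pedigree$subgroup,
                      levels = c("cMZ", "dA.MZ", "dNA.MZ",
                                 "cDZ", "dA.DZ", "dNA.DZ")))
  cat(sprintf("twin_cohort: %d individuals, %d SNPs, %d planted QTNs\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              nrow(x$qtn_truth)))
  cat("subgroup sizes (individuals):\n")
  print(tab)
  invisible(x)
}

#' Ids of unrelated undiagnosed controls in a cohort
#'
#' @param cohort A `twin_cohort`.
#' @return Character vector of individual ids.
#' @export
control_ids <- function(cohort) {
  with(cohort$pedigree,
       individual_id[zygosity == "control" & !diagnosis])
}

#' Write a cohort to disk as PED/MAP plus phenotype and truth tables
#'
#' Produces `<prefix>.ped`, `<prefix>.map` and `<prefix>.snps.tsv` (see
#' [write_plink()]), a phenotype TSV `<prefix>.pheno.tsv` (individual id,
#' pair id, zygosity, diagnosis, subgroup, then the 88 item columns) and a
#' ground-truth TSV `<prefix>.truth.tsv` (snp, trait, effect).
#'
#' @param cohort A `twin_cohort`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, prefix) {
  stopifnot(inherits(cohort, "twin_cohort"))
  fam <- data.frame(
    individual_id = cohort$pedigree$individual_id,
    family_id = ifelse(is.na(cohort$pedigree$pair_id),
                       cohort$pedigree$individual_id,
                       cohort$pedigree$pair_id),
    phenotype = ifelse(cohort$pedigree$diagnosis, 2L, 1L),
    stringsAsFactors = FALSE)
  paths <- write_plink(cohort$genotypes, prefix, fam = fam)
  pheno_path <- paste0(prefix, ".pheno.tsv")
  truth_path <- paste0(prefix, ".truth.tsv")
  utils::write.table(cohort$item_scores, pheno_path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  utils::write.table(cohort$qtn_truth, truth_path, quote = FALSE,
                     sep = "\t", row.names = FALSE)
  invisible(c(paths, pheno = pheno_path, truth = truth_path))
}
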