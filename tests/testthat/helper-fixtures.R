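# Shared fixture builders; everything is generated in code, nothing on disk.

# genotype_matrix from a bare dosage matrix (auto ids and snp metadata)
make_g <- function(dosage, chrom = NULL, bp = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("I%03d", 1:n)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("s%03d", 1:m)
  snps <- data.frame(snp = colnames(dosage),
                     chrom = if (is.null(chrom)) rep("1", m) else chrom,
                     bp = if (is.null(bp)) seq_len(m) * 1000L else bp,
                     minor = rep("A", m), major = rep("G", m),
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps)
}

# small item table: n individuals per subgroup, item scores emitted from
# given per-subgroup liability means through the package generator
make_item_table <- function(means, n_per_group, trait_map = default_trait_map(),
                            noise_sd = 0.5, seed = 1) {
  groups <- names(means)
  n <- n_per_group * length(groups)
  liab <- matrix(rep(unlist(means), each = n_per_group), n, 5)
  colnames(liab) <- asd_traits()
  rownames(liab) <- sprintf("I%03d", 1:n)
  items <- liabilities_to_item_scores(liab, trait_map, noise_sd = noise_sd,
                                      seed = seed)
  cbind(data.frame(individual_id = rownames(liab),
                   pair_id = NA_character_, zygosity = "control",
                   diagnosis = FALSE,
                   subgroup = rep(groups, each = n_per_group),
                   stringsAsFactors = FALSE),
        as.data.frame(items))
}

# tiny trait map (3 items, one trait) for closed-form scoring checks
tiny_trait_map <- function() {
  data.frame(item = c("item_01", "item_02", "item_03"),
             trait = "spoken_language", stringsAsFactors = FALSE)
}
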