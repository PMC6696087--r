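#' Simulate a gene annotation covering a marker map
#'
#' Lays non-overlapping synthetic genes along each chromosome of a SNP
#' table so nearest-gene mapping and enrichment can be exercised without
#' an external annotation. Gene symbols are `G<chrom>_<index>`.
#'
#' @param snps SNP table (`snp`, `chrom`, `bp`).
#' @param gene_length Gene length in bp (default 6000).
#' @param gap Gap between consecutive genes in bp (default 4000).
#' @return Data frame `chrom`, `start`, `end`, `symbol` (0-based
#'   half-open).
#' @export
simulate_gene_annotation <- function(snps, gene_length = 6000L,
                                     gap = 4000L) {
  rows <- lapply(split(snps, snps$chrom), function(s) {
    span <- max(s$bp) + gene_length
    starts <- seq(0L, span, by = gene_length + gap)
    data.frame(chrom = s$chrom[1], start = starts,
               end = starts + gene_length,
               symbol = sprintf("G%s_%04d", s$chrom[1], seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Collects every stage threshold of the end-to-end workflow with the
#' published defaults: QC at call rate 0.95 / MAF 0.05 / HWE p 0.001,
#' QTN screening at p <= 1e-5, stratified case-control at BH FDR <= 0.10,
#' and the discordant-DZ nominal filter at p <= 0.05 with OR >= 3.
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param trait_map Item-to-trait map.
#' @param subgroups Subgroup labels to analyse.
#' @param qtl_alpha QTN screening threshold.
#' @param fdr BH FDR threshold for the stratified case-control stage.
#' @param min_call_rate,min_maf,hwe_p QC thresholds.
#' @param dz_p,dz_or Discordant-DZ nominal filter.
#' @param quartile_method Passed to [quartile_thresholds()].
#' @param reference_sets Optional named list of reference gene-symbol
#'   vectors for enrichment.
#' @param seed Master seed (overrides `sim$rng_seed`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            trait_map = default_trait_map(),
                            subgroups = c("cMZ", "dA.MZ", "dNA.MZ",
                                          "cDZ", "dA.DZ", "dNA.DZ"),
                            qtl_alpha = 1e-5, fdr = 0.10,
                            min_call_rate = 0.95, min_maf = 0.05,
                            hwe_p = 0.001, dz_p = 0.05, dz_or = 3.0,
                            quartile_method = "tukey_hinge",
                            reference_sets = NULL, seed = NULL) {
  if (!is.null(seed)) sim$rng_seed <- as.integer(seed)
  stopifnot(inherits(sim, "sim_config"))
  if (qtl_alpha <= 0 || qtl_alpha > 1 || fdr < 0 || fdr > 1 ||
      dz_p < 0 || dz_p > 1 || dz_or < 0)
    stop_invalid("pipeline thresholds out of range")
  structure(list(sim = sim, trait_map = trait_map, subgroups = subgroups,
                 qtl_alpha = qtl_alpha, fdr = fdr,
                 min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p = hwe_p, dz_p = dz_p, dz_or = dz_or,
                 quartile_method = quartile_method,
                 reference_sets = reference_sets),
            class = "pipeline_config")
}

write_stage_tsv <- function(x, out_dir, name) {
  if (is.null(out_dir) || is.null(x) || !nrow(x)) return(invisible(NULL))
  utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                     quote = FALSE, sep = "\t", row.names = FALSE)
}

#' Run the full trait-stratified association workflow
#'
#' Executes the stages in order: cohort simulation, item-score adjustment
#' and cumulative trait scoring, marker QC, per-(trait, subgroup) QTL
#' scans with QTN screening, quartile stratification and case-control
#' association of Q1/Q4 extremes against unrelated controls with
#' quartile odds-ratio contrasts, the discordant-DZ case-versus-co-twin
#' analysis, and nearest-gene mapping with hypergeometric enrichment.
#' All stage outputs are plain TSV; a JSON manifest records seeds,
#' thresholds and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSVs and
#'   `manifest.json`; created if needed. `NULL` keeps everything
#'   in memory.
#' @return An object of class `twinstrat_run`: the cohort, scores, QC
#'   report, per-stage tables and the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cohort <- simulate_cohort(config$sim, config$trait_map)
  items <- adjust_item_scores(cohort$item_scores)
  scores <- cumulative_trait_scores(items, config$trait_map)
  ctrl <- control_ids(cohort)

  est_ids <- qc_estimation_ids(cohort$pedigree)
  qc <- apply_qc(cohort$genotypes, config$min_call_rate, config$min_maf,
                 config$hwe_p, freq_individuals = est_ids)
  g <- qc$genotypes

  traits <- unique(config$trait_map$trait)
  qtn_rows <- list(); cc_rows <- list(); contrast_rows <- list()
  counts <- list()
  for (tr in traits) {
    for (sg in config$subgroups) {
      in_sg <- !is.na(scores$subgroup) & scores$subgroup == sg
      if (sum(in_sg) < 4L) next
      scan <- run_qtl_scan(g, scores, tr, subgroup = sg)
      qtns <- suppressWarnings(select_qtns(scan, config$qtl_alpha))
      counts[[paste(tr, sg, sep = ".")]] <-
        c(n_individuals = sum(in_sg), n_snps = nrow(scan),
          n_qtns = nrow(qtns))
      if (!nrow(qtns)) next
      qtns$trait <- tr; qtns$subgroup <- sg
      qtn_rows[[paste(tr, sg)]] <- qtns

      thr <- quartile_thresholds(scores[[tr]][in_sg],
                                 method = config$quartile_method)
      ext <- suppressWarnings(
        select_extremes(scores, tr, thr, subgroup = sg))
      cc <- suppressWarnings(
        run_stratified_cc(g, qtns, ext$q1_ids, ext$q4_ids, ctrl,
                          fdr = config$fdr))
      if (!is.null(cc$results) && nrow(cc$results)) {
        cc$results$trait <- tr; cc$results$subgroup <- sg
        cc_rows[[paste(tr, sg)]] <- cc$results
      }
      if (nrow(cc$contrasts)) {
        cc$contrasts$trait <- tr; cc$contrasts$subgroup <- sg
        contrast_rows[[paste(tr, sg)]] <- cc$contrasts
      }
    }
  }
  qtn_table <- if (length(qtn_rows)) do.call(rbind, qtn_rows)
  cc_table <- if (length(cc_rows)) do.call(rbind, cc_rows)
  contrast_table <- if (length(contrast_rows)) do.call(rbind, contrast_rows)

  ped <- cohort$pedigree
  dz_cases <- ped$individual_id[!is.na(ped$subgroup) & ped$subgroup == "dA.DZ"]
  dz_ctrls <- ped$individual_id[!is.na(ped$subgroup) & ped$subgroup == "dNA.DZ"]
  dz_table <- NULL
  if (length(dz_cases) && length(dz_ctrls))
    dz_table <- dz_discordant_cc(g, dz_cases, dz_ctrls,
                                 p_cut = config$dz_p, or_cut = config$dz_or)

  annotation <- simulate_gene_annotation(g$snps)
  universe <- unique(annotation$symbol)
  trait_genes <- list(); enr_table <- NULL
  if (!is.null(cc_table) && nrow(cc_table)) {
    sig <- cc_table[cc_table$significant, , drop = FALSE]
    for (tr in unique(sig$trait)) {
      snps_tr <- unique(sig$snp[sig$trait == tr])
      mp <- suppressWarnings(
        map_snps_to_genes(g$snps[g$snps$snp %in% snps_tr, , drop = FALSE],
                          annotation))
      trait_genes[[tr]] <- unique(mp$mapping$symbol)
    }
    if (!is.null(config$reference_sets)) {
      enr <- list()
      for (tr in names(trait_genes)) {
        if (!length(trait_genes[[tr]])) next
        for (rs in names(config$reference_sets))
          enr[[paste(tr, rs)]] <- enrich(trait_genes[[tr]],
                                         config$reference_sets[[rs]],
                                         universe, query_name = tr,
                                         reference_name = rs)
      }
      if (length(enr)) enr_table <- do.call(rbind, enr)
    }
  }
  overlap <- if (length(trait_genes) >= 2L) trait_set_overlap(trait_genes)

  manifest <- list(
    seed = config$sim$rng_seed,
    thresholds = list(qtl_alpha = config$qtl_alpha, fdr = config$fdr,
                      min_call_rate = config$min_call_rate,
                      min_maf = config$min_maf, hwe_p = config$hwe_p,
                      dz_p = config$dz_p, dz_or = config$dz_or),
    cohort = list(n_individuals = nrow(cohort$genotypes$dosage),
                  n_mz_pairs = config$sim$n_mz_pairs,
                  n_dz_pairs = config$sim$n_dz_pairs,
                  n_controls = config$sim$n_controls,
                  subgroup_sizes = as.list(table(ped$subgroup))),
    qc = as.list(qc$report$counts),
    scans = counts,
    n_qtns_total = if (is.null(qtn_table)) 0L else nrow(qtn_table),
    n_cc_rows = if (is.null(cc_table)) 0L else nrow(cc_table),
    n_cc_significant = if (is.null(cc_table)) 0L
                       else sum(cc_table$significant),
    n_contrasts = if (is.null(contrast_table)) 0L else nrow(contrast_table),
    dz = list(n_cases = length(dz_cases), n_controls = length(dz_ctrls),
              n_tested = if (is.null(dz_table)) 0L
                         else attr(dz_table, "n_tested"),
              n_nominal = if (is.null(dz_table)) 0L
                          else attr(dz_table, "n_nominal"),
              n_selected = if (is.null(dz_table)) 0L else nrow(dz_table)))

  if (!is.null(out_dir)) {
    write_stage_tsv(scores, out_dir, "trait_scores")
    write_stage_tsv(qc$report$table, out_dir, "qc_report")
    write_stage_tsv(qtn_table, out_dir, "qtns")
    write_stage_tsv(cc_table, out_dir, "case_control")
    write_stage_tsv(contrast_table, out_dir, "quartile_contrasts")
    write_stage_tsv(dz_table, out_dir, "dz_discordant")
    write_stage_tsv(enr_table, out_dir, "enrichment")
    if (!is.null(overlap))
      write_stage_tsv(overlap$regions, out_dir, "venn_regions")
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(cohort = cohort, scores = scores, qc_report = qc$report,
                 genotypes = g, qtns = qtn_table, case_control = cc_table,
                 contrasts = contrast_table, dz_discordant = dz_table,
                 trait_genes = trait_genes, enrichment = enr_table,
                 overlap = overlap, manifest = manifest,
                 config = config),
            class = "twinstrat_run")
}

#' @export
print.twinstrat_run <- function(x, ...) {
  m <- x$manifest
  cat("twinstrat pipeline run\n")
  cat(sprintf("  cohort: %d individuals (%d MZ + %d DZ pairs, %d controls)\n",
              m$cohort$n_individuals, m$cohort$n_mz_pairs,
              m$cohort$n_dz_pairs, m$cohort$n_controls))
  cat(sprintf("  QC: %d/%d SNPs survive\n", m$qc$surviving, m$qc$input))
  cat(sprintf("  QTNs: %d | case-control rows: %d (significant: %d) | contrasts: %d\n",
              m$n_qtns_total, m$n_cc_rows, m$n_cc_significant,
              m$n_contrasts))
  cat(sprintf("  discordant-DZ: %d/%d SNPs pass p<=%.2f & OR>=%.1f\n",
              m$dz$n_selected, m$dz$n_tested,
              x$config$dz_p, x$config$dz_or))
  invisible(x)
}
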