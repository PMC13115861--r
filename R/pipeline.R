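#' Run the full integrative analysis
#'
#' Executes the stages in order: contact consensus from replicate
#' fractions; per-condition SE consensus + tissue-specificity
#' classification; contact confirmation of the focal lncRNA's correlation
#' peaks and psi/omega labelling; contact density and its one-sided
#' Mann-Whitney comparison; both permutation enrichment tests; the
#' multi-lncRNA SE-overlap ranking; target-gene assignment, lead genes and
#' the cohort Welch DE; co-expression with the random-gene-set null
#' (ordinary and purity-corrected) and the triple-validation filter.
#'
#' @param inputs input bundle as produced by [simulate_study()]`$inputs` or
#'   [load_study_inputs()]
#' @param seed integer seed driving the permutation and resampling tests
#' @param params named list overriding analysis parameters: pad,
#'   contact_min_support, intra_gap, cross_gap, cancer_min_support,
#'   normal_min_support, min_overlap_bp, window, tpm_min, promoter_pad,
#'   alpha, n_iter, n_sets
#' @return a `run_report` list with per-stage tables, statistics and a
#'   `counts` summary
#' @export
run_pipeline <- function(inputs, seed, params = list()) {
  p <- utils::modifyList(list(
    pad = 250, contact_min_support = 2, intra_gap = 12500, cross_gap = 0,
    cancer_min_support = NULL, normal_min_support = NULL,
    min_overlap_bp = 1, window = 100000, tpm_min = 1, promoter_pad = 2000,
    alpha = 0.05, n_iter = 1000, n_sets = 10000), params)
  sizes <- inputs$sizes

  ## stage 1: consensus contact peaks
  contacts <- contact_consensus(inputs$fractions, sizes, pad = p$pad,
                                min_support = p$contact_min_support,
                                blacklist = inputs$blacklist)

  ## stage 2: SE atlas
  is_cancer <- vapply(inputs$se_samples, function(s) s$condition == "cancer",
                      logical(1))
  cs <- inputs$se_samples[is_cancer]
  ns <- inputs$se_samples[!is_cancer]
  if (is.null(p$cancer_min_support)) p$cancer_min_support <- length(cs)
  if (is.null(p$normal_min_support)) p$normal_min_support <-
      max(1, length(ns) - 1)
  cancer_cons <- build_condition_consensus(cs, p$cancer_min_support,
                                           intra_gap = p$intra_gap,
                                           cross_gap = p$cross_gap,
                                           id_prefix = "se_")
  normal_cons <- build_condition_consensus(ns, p$normal_min_support,
                                           intra_gap = p$intra_gap,
                                           cross_gap = p$cross_gap,
                                           id_prefix = "nse_")
  atlas <- classify_specificity(cancer_cons, normal_cons,
                                min_overlap_bp = p$min_overlap_bp)
  cancer_specific <- atlas$cancer[atlas$cancer$specificity == "cancer-specific",
                                  , drop = FALSE]

  ## stage 3: confirmation + psi/omega labels
  focal_peaks <- inputs$corr_peaks[inputs$corr_peaks$lncrna_id ==
                                     inputs$focal_id, , drop = FALSE]
  confirmed <- confirm_peaks(focal_peaks, contacts)
  cls <- classify_ses(cancer_specific, confirmed)
  density <- contact_density(cls$ses, contacts)
  dens_psi <- density$n_contacts[cls$ses$psi == "psi"]
  dens_other <- density$n_contacts[cls$ses$psi == "omega" &
                                     density$n_contacts >= 1]
  mw <- if (length(dens_psi) > 0 && length(dens_other) > 0) {
    mann_whitney_one_sided(dens_psi, dens_other)
  } else NULL

  ## stage 4: permutation tests
  perm_overlap <- permute_overlap_enrichment(
    cancer_specific, contacts, sizes, seed = seed, n_iter = p$n_iter)
  perm_triple <- permute_triple_enrichment(
    cancer_specific, focal_peaks, contacts, sizes, seed = seed + 1,
    n_iter = p$n_iter)

  ## stage 5: lncRNA ranking (skipped when the focal lncRNA has no peaks)
  ranking <- if (inputs$focal_id %in% inputs$corr_peaks$lncrna_id) {
    lncrna_se_ranking(inputs$corr_peaks, cancer_specific, inputs$focal_id)
  } else NULL

  ## stage 6: targets + expression evidence
  assocs <- assign_targets(cancer_specific, inputs$genes, window = p$window,
                           tpm_min = p$tpm_min, tpm_col = "tpm_cancer")
  leads <- lead_gene(assocs, inputs$de_cell, alpha = p$alpha)
  tssm <- tss_mode(cls$ses, confirmed, inputs$genes, assocs,
                   promoter_pad = p$promoter_pad)

  cohort_expr <- inputs$cohort$expr
  cohort_meta <- inputs$cohort$meta
  de_cohort <- welch_de(cohort_expr, cohort_meta$class)
  tumor_expr <- cohort_expr[, cohort_meta$class == "tumor", drop = FALSE]
  tumor_purity <- cohort_meta$purity[cohort_meta$class == "tumor"]

  ## stage 7: co-expression + triple validation
  psi_assocs <- assocs[assocs$se_id %in% cls$ses$se_id[cls$ses$psi == "psi"],
                       , drop = FALSE]
  target_genes <- unique(psi_assocs$gene_id)
  evaluable <- intersect(target_genes, rownames(tumor_expr))
  coexpr <- if (length(evaluable) > 0) {
    coexpr_table(tumor_expr, inputs$focal_id, gene_ids = evaluable,
                 purity = tumor_purity)
  } else {
    data.frame(gene_id = character(), rho = numeric(), p = numeric(),
               fdr = numeric(), n = integer(), stringsAsFactors = FALSE)
  }
  geneset_null <- geneset_null_pur <- NULL
  if (length(evaluable) >= 2) {
    geneset_null <- random_geneset_null(
      tumor_expr, inputs$focal_id, evaluable, seed = seed + 2,
      n_sets = p$n_sets, alpha = p$alpha)
    geneset_null_pur <- random_geneset_null(
      tumor_expr, inputs$focal_id, evaluable, seed = seed + 3,
      n_sets = p$n_sets, alpha = p$alpha, purity = tumor_purity)
  }
  validated <- triple_validate(psi_assocs, inputs$de_cell, de_cohort,
                               coexpr, alpha = p$alpha)

  n_psi <- sum(cls$ses$psi == "psi")
  counts <- list(
    n_contact_peaks = nrow(contacts),
    n_focal_corr_peaks = nrow(focal_peaks),
    n_confirmed_peaks = nrow(confirmed),
    pct_confirmed = summarize_percentage(nrow(confirmed), nrow(focal_peaks)),
    n_consensus_se = atlas$summary$n_total,
    n_cancer_specific = atlas$summary$n_cancer_specific,
    n_normal_specific = atlas$summary$n_normal_specific,
    n_shared = atlas$summary$n_shared,
    n_psi = n_psi,
    n_omega = nrow(cls$ses) - n_psi,
    pct_psi = summarize_percentage(n_psi, nrow(cls$ses)),
    pct_omega = summarize_percentage(nrow(cls$ses) - n_psi, nrow(cls$ses)),
    n_se_contacted = sum(density$n_contacts > 0),
    pct_se_contacted = summarize_percentage(sum(density$n_contacts > 0),
                                            nrow(cls$ses)),
    n_associations = nrow(assocs),
    n_psi_associations = nrow(psi_assocs),
    n_lead_genes = nrow(leads$leads),
    n_triple_validated = length(unique(
      validated$gene_id[validated$triple_validated])),
    n_tss_mode_ses = length(unique(tssm$tss_hits$se_id)))

  structure(list(
    params = p, seed = seed, counts = counts,
    contacts = contacts, atlas = atlas, confirmed = confirmed,
    classification = cls, density = density, mann_whitney = mw,
    perm_overlap = perm_overlap, perm_triple = perm_triple,
    ranking = ranking, assocs = assocs, leads = leads, tss_mode = tssm,
    de_cohort = de_cohort, coexpr = coexpr,
    geneset_null = geneset_null, geneset_null_purity = geneset_null_pur,
    validated = validated), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  c <- x$counts
  cat("Integrative lncRNA-SE run report\n")
  cat(sprintf("  consensus contact peaks:     %d\n", c$n_contact_peaks))
  cat(sprintf("  consensus SEs:               %d (%d cancer-specific / %d normal-specific / %d shared)\n",
              c$n_consensus_se, c$n_cancer_specific, c$n_normal_specific,
              c$n_shared))
  cat(sprintf("  confirmed correlation peaks: %d of %d (%.1f%%)\n",
              c$n_confirmed_peaks, c$n_focal_corr_peaks, c$pct_confirmed))
  cat(sprintf("  psi SEs:                     %d of %d (%.1f%%); omega %d (%.1f%%)\n",
              c$n_psi, c$n_psi + c$n_omega, c$pct_psi, c$n_omega, c$pct_omega))
  cat(sprintf("  SE overlap permutation:      p = %s, fold = %.2f\n",
              format_empirical_p(x$perm_overlap$observed, x$perm_overlap$null),
              round_half_up(x$perm_overlap$fold, 2)))
  cat(sprintf("  triple permutation:          p = %s, fold = %.2f\n",
              format_empirical_p(x$perm_triple$observed, x$perm_triple$null),
              round_half_up(x$perm_triple$fold, 2)))
  if (!is.null(x$ranking)) {
    cat(sprintf("  focal lncRNA SE percentile:  %.0f (count %d over %d lncRNAs)\n",
                x$ranking$percentile, x$ranking$focal_count,
                x$ranking$n_with_overlap))
  }
  cat(sprintf("  associations:                %d (%d at psi SEs), %d lead genes\n",
              c$n_associations, c$n_psi_associations, c$n_lead_genes))
  cat(sprintf("  triple-validated genes:      %d\n", c$n_triple_validated))
  invisible(x)
}

#' Write the run report as JSON and TSV
#'
#' Every number in the emitted files is recomputable from the stage tables
#' alone; the JSON carries the scalar summaries, the TSVs the per-record
#' tables.
#'
#' @param report a `run_report`
#' @param dir output directory (created if needed)
#' @return dir, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scal <- c(report$counts, list(
    perm_overlap = unclass(report$perm_overlap)[
      c("observed", "null_mean", "null_sd", "null_range", "p", "fold",
        "n_iter", "seed")],
    perm_triple = unclass(report$perm_triple)[
      c("observed", "null_mean", "null_sd", "null_range", "p", "fold",
        "n_iter", "seed")],
    ranking_percentile = if (is.null(report$ranking)) NULL else
      report$ranking$percentile,
    seed = report$seed, params = report$params))
  if (!is.null(report$mann_whitney)) {
    scal$mann_whitney <- report$mann_whitney[c("U", "p")]
  }
  jsonlite::write_json(scal, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv_table(report$classification$ses, file.path(dir, "se_classification.tsv"))
  write_tsv_table(report$classification$profiles, file.path(dir, "mark_profiles.tsv"))
  write_tsv_table(report$assocs, file.path(dir, "associations.tsv"))
  write_tsv_table(report$leads$leads, file.path(dir, "lead_genes.tsv"))
  write_tsv_table(report$validated, file.path(dir, "triple_validation.tsv"))
  write_tsv_table(report$coexpr, file.path(dir, "coexpression.tsv"))
  if (!is.null(report$ranking)) {
    write_tsv_table(report$ranking$counts, file.path(dir, "lncrna_ranking.tsv"))
  }
  write_tsv_table(report$tss_mode$tss_hits, file.path(dir, "tss_mode.tsv"))
  write_bed(report$contacts[, c("chrom", "start", "end", "name")],
            file.path(dir, "consensus_contacts.bed"))
  invisible(dir)
}

#' Write a simulated input bundle to disk
#'
#' Emits the whole bundle in the plain-text formats the readers consume:
#' narrowPeak/BED fraction files plus a manifest, a blacklist BED, SE
#' sample BEDs plus a manifest, chrom.sizes, the correlation peak TSV, gene
#' table, TPM matrices, DE table, cohort matrix and metadata, and the
#' ground truth as JSON.
#'
#' @param sim output of [simulate_study()]
#' @param dir output directory
#' @return dir, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inp <- sim$inputs
  write_chrom_sizes(inp$sizes, file.path(dir, "genome.chrom.sizes"))
  write_bed(inp$blacklist, file.path(dir, "blacklist.bed"))
  man <- list()
  for (rep_id in names(inp$fractions)) {
    for (f in names(inp$fractions[[rep_id]])) {
      fn <- sprintf("contacts_%s_%s.narrowPeak", rep_id, f)
      write_narrowpeak(inp$fractions[[rep_id]][[f]]$peaks, file.path(dir, fn))
      man[[length(man) + 1]] <- data.frame(replicate = rep_id, fraction = f,
                                           path = fn)
    }
  }
  write_tsv_table(do.call(rbind, man), file.path(dir, "fraction_manifest.tsv"))
  se_man <- list()
  for (s in inp$se_samples) {
    fn <- sprintf("se_%s.bed", s$sample_id)
    write_bed(s$ses, file.path(dir, fn))
    se_man[[length(se_man) + 1]] <- data.frame(sample = s$sample_id,
                                               condition = s$condition,
                                               path = fn)
  }
  write_tsv_table(do.call(rbind, se_man), file.path(dir, "se_manifest.tsv"))
  write_tsv_table(inp$corr_peaks, file.path(dir, "correlation_peaks.tsv"))
  write_tsv_table(inp$genes, file.path(dir, "genes.tsv"))
  write_expression_matrix(inp$tpm_cell$cancer, file.path(dir, "tpm_cell_cancer.tsv"))
  write_expression_matrix(inp$tpm_cell$normal, file.path(dir, "tpm_cell_normal.tsv"))
  write_tsv_table(inp$de_cell, file.path(dir, "de_cell.tsv"))
  write_expression_matrix(inp$cohort$expr, file.path(dir, "cohort_expr.tsv"))
  write_tsv_table(inp$cohort$meta, file.path(dir, "cohort_meta.tsv"))
  writeLines(inp$focal_id, file.path(dir, "focal_id.txt"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a simulated (or equivalently formatted) input bundle
#'
#' Counterpart of [write_simulation()]; returns the same `inputs` shape
#' that [run_pipeline()] consumes.
#'
#' @param dir directory written by [write_simulation()]
#' @return inputs list
#' @export
load_study_inputs <- function(dir) {
  fractions <- read_fraction_manifest(file.path(dir, "fraction_manifest.tsv"))
  se_samples <- read_se_manifest(file.path(dir, "se_manifest.tsv"))
  list(
    sizes = read_chrom_sizes(file.path(dir, "genome.chrom.sizes")),
    fractions = fractions,
    blacklist = read_bed(file.path(dir, "blacklist.bed")),
    se_samples = se_samples,
    corr_peaks = read_tsv_table(file.path(dir, "correlation_peaks.tsv")),
    genes = read_tsv_table(file.path(dir, "genes.tsv")),
    tpm_cell = list(
      cancer = read_expression_matrix(file.path(dir, "tpm_cell_cancer.tsv")),
      normal = read_expression_matrix(file.path(dir, "tpm_cell_normal.tsv"))),
    de_cell = read_tsv_table(file.path(dir, "de_cell.tsv")),
    cohort = list(
      expr = read_expression_matrix(file.path(dir, "cohort_expr.tsv")),
      meta = read_tsv_table(file.path(dir, "cohort_meta.tsv"))),
    focal_id = readLines(file.path(dir, "focal_id.txt"))[1])
}
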