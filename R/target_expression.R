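#' Assign candidate target genes to super-enhancers
#'
#' A gene is associated with an SE iff it is expressed (mean TPM strictly
#' greater than `tpm_min` in the analysis condition) and either its
#' interval overlaps the SE by >= 1 bp or its annotation start coordinate
#' lies within `window` bp (inclusive) of the nearer SE boundary. Distance
#' is 0 for overlapping genes, otherwise
#' `min(|gene_start - se_end|, |se_start - gene_start|)` in half-open
#' coordinates. The gene "start" is the annotation start regardless of
#' strand.
#'
#' @param ses consensus SE data.frame (se_id, chrom, start, end, ...)
#' @param genes gene table with gene_id, symbol, chrom, start, end, strand,
#'   biotype and the TPM column named by `tpm_col`
#' @param window association window in bp (default 100,000, inclusive)
#' @param tpm_min expression threshold (strict >, default 1)
#' @param tpm_col which TPM column defines "expressed" (default
#'   "tpm_cancer")
#' @param biotypes biotypes eligible as targets (default "protein_coding")
#' @return data.frame: se_id, gene_id, symbol, distance, tpm
#' @export
assign_targets <- function(ses, genes, window = 100000, tpm_min = 1,
                           tpm_col = "tpm_cancer",
                           biotypes = "protein_coding") {
  stopifnot(tpm_col %in% names(genes))
  empty <- data.frame(se_id = character(), gene_id = character(),
                      symbol = character(), distance = numeric(),
                      tpm = numeric(), stringsAsFactors = FALSE)
  g <- genes
  if (!is.null(biotypes)) g <- g[g$biotype %in% biotypes, , drop = FALSE]
  g <- g[g[[tpm_col]] > tpm_min, , drop = FALSE]
  if (nrow(g) == 0 || nrow(ses) == 0) return(empty)
  se_gr <- bed_to_gr(ses)
  body_hits <- GenomicRanges::findOverlaps(
    se_gr, bed_to_gr(g[, c("chrom", "start", "end")]))
  # gene starts as 1-bp points against SEs padded by `window` (left) and
  # `window` + 1 (right) so that |gene_start - se_end| == window is included
  pad_df <- data.frame(chrom = ses$chrom,
                       start = pmax(0, ses$start - window),
                       end = ses$end + window + 1, stringsAsFactors = FALSE)
  pt_df <- data.frame(chrom = g$chrom, start = g$start, end = g$start + 1,
                      stringsAsFactors = FALSE)
  win_hits <- GenomicRanges::findOverlaps(bed_to_gr(pad_df), bed_to_gr(pt_df))
  pairs <- unique(rbind(
    data.frame(se = S4Vectors::queryHits(body_hits),
               gene = S4Vectors::subjectHits(body_hits)),
    data.frame(se = S4Vectors::queryHits(win_hits),
               gene = S4Vectors::subjectHits(win_hits))))
  if (nrow(pairs) == 0) return(empty)
  se_start <- ses$start[pairs$se]; se_end <- ses$end[pairs$se]
  g_start <- g$start[pairs$gene]; g_end <- g$end[pairs$gene]
  overlap <- g_start < se_end & g_end > se_start
  distance <- ifelse(overlap, 0,
                     pmin(abs(g_start - se_end), abs(se_start - g_start)))
  keep <- overlap | distance <= window
  out <- data.frame(se_id = ses$se_id[pairs$se[keep]],
                    gene_id = g$gene_id[pairs$gene[keep]],
                    symbol = g$symbol[pairs$gene[keep]],
                    distance = distance[keep],
                    tpm = g[[tpm_col]][pairs$gene[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$se_id, out$distance, out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Designate the lead gene of each super-enhancer
#'
#' The lead gene is the associated target with the lowest adjusted
#' differential-expression p-value; genes missing from the DE table are
#' treated as padj = 1 with a warning. Ties are broken by larger |log2FC|,
#' then lexicographic gene id. A lead gene may be non-significant; it is
#' flagged. SEs without associations simply have no lead row.
#'
#' @param assocs association table from [assign_targets()]
#' @param de differential-expression table (gene_id, log2FC, padj)
#' @param alpha significance threshold on padj (default 0.05)
#' @return list: `assocs` with `lead` flag and DE columns; `leads` one row
#'   per SE with >= 1 target (se_id, gene_id, symbol, log2FC, padj,
#'   significant)
#' @export
lead_gene <- function(assocs, de, alpha = 0.05) {
  a <- merge(assocs, de[, c("gene_id", "log2FC", "padj")], by = "gene_id",
             all.x = TRUE, sort = FALSE)
  missing <- unique(a$gene_id[is.na(a$padj)])
  if (length(missing) > 0) {
    warning(sprintf("%d associated gene(s) missing from the DE table; treated as padj = 1: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    a$padj[is.na(a$padj)] <- 1
    a$log2FC[is.na(a$log2FC)] <- 0
  }
  a <- a[order(a$se_id, a$padj, -abs(a$log2FC), a$gene_id, method = "radix"), ]
  a$lead <- !duplicated(a$se_id)
  rownames(a) <- NULL
  leads <- a[a$lead, c("se_id", "gene_id", "symbol", "log2FC", "padj"),
             drop = FALSE]
  leads$significant <- leads$padj < alpha
  rownames(leads) <- NULL
  list(assocs = a, leads = leads)
}

#' Genome-wide Welch's t-test on log2(TPM + 1) values
#'
#' Per-gene two-sample Welch statistic with Satterthwaite degrees of
#' freedom and two-sided p; `log2FC` is the difference of group means on
#' the log2(TPM + 1) scale (tumor minus normal). Zero variance in both
#' groups with equal means yields t = 0, p = 1. p-values are BH-adjusted.
#'
#' @param expr genes x samples matrix of log2(TPM + 1) values
#' @param groups factor/character of "tumor"/"normal" per column
#' @return data.frame: gene_id, log2FC, t, df, p, padj
#' @export
welch_de <- function(expr, groups) {
  stopifnot(ncol(expr) == length(groups))
  is_t <- groups == "tumor"; is_n <- groups == "normal"
  n1 <- sum(is_t); n0 <- sum(is_n)
  if (n1 < 2 || n0 < 2) stop("need >= 2 samples per group")
  x1 <- expr[, is_t, drop = FALSE]; x0 <- expr[, is_n, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    same <- degen & (m1 == m0)
    tstat[same] <- 0; p[same] <- 1; df[same] <- NA
    diff <- degen & (m1 != m0)
    tstat[diff] <- sign(m1 - m0)[diff] * Inf; p[diff] <- 0; df[diff] <- NA
  }
  data.frame(gene_id = rownames(expr), log2FC = m1 - m0, t = tstat, df = df,
             p = p, padj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Triple-validation filter over SE-gene associations
#'
#' Requires concordant evidence across three layers: upregulation in the
#' cancer cell line (padj < alpha and log2FC > 0), upregulation in the
#' tumor cohort (p < alpha and log2FC > 0), and positive co-expression
#' with the focal lncRNA (rho > 0 and unadjusted p < alpha; the FDR is
#' carried alongside for reporting). A gene missing from any table fails
#' that layer (with a message).
#'
#' @param assocs association table (must have gene_id, se_id)
#' @param de_cell cell-line DE table (gene_id, log2FC, padj)
#' @param de_cohort cohort DE table (gene_id, log2FC, p)
#' @param coexpr co-expression table (gene_id, rho, p, fdr)
#' @param alpha significance level (default 0.05)
#' @return `assocs` with flags cell_up, cohort_up, coexpr_pos,
#'   triple_validated, plus the evidence columns
#' @export
triple_validate <- function(assocs, de_cell, de_cohort, coexpr, alpha = 0.05) {
  a <- assocs
  pick <- function(tab, cols, prefix) {
    idx <- match(a$gene_id, tab$gene_id)
    if (anyNA(idx)) {
      message(sprintf("%d gene(s) not mappable in the %s table; failing that layer",
                      sum(is.na(idx)), prefix))
    }
    out <- tab[idx, cols, drop = FALSE]
    names(out) <- paste0(prefix, "_", cols)
    out
  }
  a <- cbind(a, pick(de_cell, c("log2FC", "padj"), "cell"))
  a <- cbind(a, pick(de_cohort, c("log2FC", "p"), "cohort"))
  a <- cbind(a, pick(coexpr, c("rho", "p", "fdr"), "coexpr"))
  flag <- function(x) !is.na(x) & x
  a$cell_up <- flag(a$cell_padj < alpha & a$cell_log2FC > 0)
  a$cohort_up <- flag(a$cohort_p < alpha & a$cohort_log2FC > 0)
  a$coexpr_pos <- flag(a$coexpr_rho > 0 & a$coexpr_p < alpha)
  a$triple_validated <- a$cell_up & a$cohort_up & a$coexpr_pos
  a
}
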