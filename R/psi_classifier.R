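HISTONE_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K27me3",
                   "H3K36me3", "H3K9me3", "H4K20me1")

#' Validate a lncRNA-histone-mark correlation peak table
#'
#' Expected columns: chrom, start, end, lncrna_id, mark, sign (and optional
#' rho). Marks must come from the seven-mark vocabulary; when both sign and
#' rho are present their signs must agree.
#'
#' @param x correlation peak data.frame
#' @return x, invisibly
#' @export
validate_correlation_peaks <- function(x) {
  validate_intervals(x)
  need <- c("lncrna_id", "mark", "sign")
  if (!all(need %in% names(x))) {
    stop("correlation peak table needs columns lncrna_id, mark, sign")
  }
  if (nrow(x) == 0) return(invisible(x))
  bad_mark <- setdiff(unique(x$mark), HISTONE_MARKS)
  if (length(bad_mark) > 0) {
    stop(sprintf("unknown histone mark '%s'", bad_mark[1]))
  }
  if (!all(x$sign %in% c("+", "-"))) stop("sign must be '+' or '-'")
  if (!is.null(x$rho)) {
    ok <- is.na(x$rho) | (x$sign == "+" & x$rho >= 0) |
      (x$sign == "-" & x$rho <= 0)
    if (!all(ok)) {
      stop(sprintf("correlation sign/value mismatch at record %d", which(!ok)[1]))
    }
  }
  invisible(x)
}

#' Contact-confirmed correlation peaks for one focal lncRNA
#'
#' Returns exactly the correlation peaks that overlap at least one consensus
#' contact peak by >= 1 bp, with coordinates and annotations unchanged
#' (report-once semantics). The input must already be restricted to a
#' single lncRNA; mixed tables are rejected to guard against unfiltered
#' input.
#'
#' @param corr_peaks correlation peak data.frame (one lncRNA)
#' @param contacts consensus contact peak data.frame
#' @return subset of `corr_peaks`
#' @export
confirm_peaks <- function(corr_peaks, contacts) {
  validate_correlation_peaks(corr_peaks)
  ids <- unique(corr_peaks$lncrna_id)
  if (length(ids) > 1) {
    stop(sprintf("correlation peaks carry %d lncRNA ids; restrict to the focal lncRNA first",
                 length(ids)))
  }
  iv_intersect_keep(corr_peaks, contacts)
}

#' Label super-enhancers as psi (lncRNA-reactive) or omega
#'
#' A super-enhancer is labeled psi iff at least one confirmed correlation
#' peak overlaps it by >= 1 bp, else omega. For psi SEs the mark profile is
#' the set of distinct (mark, sign) pairs among overlapping confirmed peaks
#' ("mark instances"), with per-pair peak counts reported separately; a
#' profile with >= 2 distinct instances is flagged compound.
#'
#' @param ses consensus SE data.frame (typically the cancer-specific set)
#' @param confirmed confirmed correlation peaks from [confirm_peaks()]
#' @return list: `ses` with a `psi` column ("psi"/"omega") and
#'   `n_confirmed_peaks`; `profiles` (se_id, mark, sign, n_peaks);
#'   `summary` (counts and one-decimal percentages)
#' @export
classify_ses <- function(ses, confirmed) {
  stopifnot(is.data.frame(ses), "se_id" %in% names(ses))
  if (nrow(ses) == 0) {
    ses$psi <- character(0)
    ses$n_confirmed_peaks <- integer(0)
    return(list(ses = ses,
                profiles = data.frame(se_id = character(), mark = character(),
                                      sign = character(), n_peaks = integer()),
                summary = data.frame(n_se = 0L, n_psi = 0L, n_omega = 0L,
                                     pct_psi = NA_real_, pct_omega = NA_real_)))
  }
  n_conf <- iv_count_overlaps(ses, confirmed)
  ses$psi <- ifelse(n_conf > 0, "psi", "omega")
  ses$n_confirmed_peaks <- as.integer(n_conf)
  profiles <- data.frame(se_id = character(), mark = character(),
                         sign = character(), n_peaks = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(confirmed) > 0 && any(n_conf > 0)) {
    hits <- GenomicRanges::findOverlaps(bed_to_gr(ses), bed_to_gr(confirmed))
    if (length(hits) > 0) {
      pairs <- data.frame(se_id = ses$se_id[S4Vectors::queryHits(hits)],
                          mark = confirmed$mark[S4Vectors::subjectHits(hits)],
                          sign = confirmed$sign[S4Vectors::subjectHits(hits)],
                          stringsAsFactors = FALSE)
      profiles <- stats::aggregate(list(n_peaks = rep(1L, nrow(pairs))),
                                   pairs[c("se_id", "mark", "sign")], sum)
      profiles <- profiles[order(profiles$se_id, profiles$mark, profiles$sign,
                                 method = "radix"), ]
      rownames(profiles) <- NULL
    }
  }
  n_se <- nrow(ses)
  n_psi <- sum(ses$psi == "psi")
  summary <- data.frame(
    n_se = n_se, n_psi = n_psi, n_omega = n_se - n_psi,
    pct_psi = summarize_percentage(n_psi, n_se),
    pct_omega = summarize_percentage(n_se - n_psi, n_se),
    n_mark_instances = nrow(profiles),
    n_compound = if (nrow(profiles) > 0) {
      sum(table(profiles$se_id) >= 2)
    } else 0L)
  list(ses = ses, profiles = profiles, summary = summary)
}

#' Contact-peak density per super-enhancer
#'
#' Counts the consensus contact peaks overlapping each SE by >= 1 bp; a peak
#' spanning two SEs is counted once per SE. Feeds the one-sided
#' Mann-Whitney comparison of psi versus other contacted SEs.
#'
#' @param ses consensus SE data.frame
#' @param contacts consensus contact peak data.frame
#' @return data.frame: se_id, n_contacts
#' @export
contact_density <- function(ses, contacts) {
  data.frame(se_id = ses$se_id,
             n_contacts = as.integer(iv_count_overlaps(ses, contacts)),
             stringsAsFactors = FALSE)
}

# TSS in BED coordinates: annotation start for + / unknown strand, the last
# base (end - 1) for - strand.
gene_tss <- function(genes) {
  unknown <- !(genes$strand %in% c("+", "-"))
  if (any(unknown)) {
    warning(sprintf("%d gene(s) with unknown strand; TSS taken as start coordinate",
                    sum(unknown)))
  }
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

#' Promoter-mode detection and SE-body/TSS concordance
#'
#' For each omega SE, reports target genes whose promoter window
#' `[TSS - pad, TSS + pad)` overlaps at least one confirmed correlation
#' peak - SEs whose lncRNA association runs through the promoter rather
#' than the SE body. Also reports, for each psi SE, whether the SE body and
#' at least one target promoter are both marked (concordance).
#'
#' @param ses classified SE data.frame (with `psi` column)
#' @param confirmed confirmed correlation peaks
#' @param genes gene table (gene_id, chrom, start, end, strand, ...)
#' @param targets association table (se_id, gene_id) from [assign_targets()]
#' @param promoter_pad promoter half-window in bp (default 2,000)
#' @return list: `tss_hits` (se_id, gene_id, mark, sign) for omega SEs;
#'   `psi_concordance` (se_id, concordant)
#' @export
tss_mode <- function(ses, confirmed, genes, targets, promoter_pad = 2000) {
  stopifnot("psi" %in% names(ses))
  genes <- genes[genes$gene_id %in% targets$gene_id, , drop = FALSE]
  empty_hits <- data.frame(se_id = character(), gene_id = character(),
                           mark = character(), sign = character(),
                           stringsAsFactors = FALSE)
  psi_ids <- ses$se_id[ses$psi == "psi"]
  if (nrow(genes) == 0 || nrow(confirmed) == 0) {
    return(list(tss_hits = empty_hits,
                psi_concordance = data.frame(se_id = psi_ids,
                                             concordant = logical(length(psi_ids)))))
  }
  tss <- gene_tss(genes)
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, tss - promoter_pad),
                     end = tss + promoter_pad,
                     gene_id = genes$gene_id, stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(bed_to_gr(prom), bed_to_gr(confirmed))
  marked <- data.frame(
    gene_id = prom$gene_id[S4Vectors::queryHits(hits)],
    mark = confirmed$mark[S4Vectors::subjectHits(hits)],
    sign = confirmed$sign[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  marked <- unique(marked)
  assoc <- merge(targets[, c("se_id", "gene_id")], marked, by = "gene_id")
  assoc <- merge(assoc, ses[, c("se_id", "psi")], by = "se_id")
  tss_hits <- assoc[assoc$psi == "omega",
                    c("se_id", "gene_id", "mark", "sign"), drop = FALSE]
  tss_hits <- tss_hits[order(tss_hits$se_id, tss_hits$gene_id,
                             tss_hits$mark, method = "radix"), , drop = FALSE]
  rownames(tss_hits) <- NULL
  if (nrow(tss_hits) == 0) tss_hits <- empty_hits
  conc <- data.frame(se_id = psi_ids,
                     concordant = psi_ids %in% assoc$se_id[assoc$psi == "psi"],
                     stringsAsFactors = FALSE)
  list(tss_hits = tss_hits, psi_concordance = conc)
}

#' Rank a focal lncRNA by super-enhancer coverage of its correlation peaks
#'
#' For every lncRNA in the table, counts the SEs harbouring at least one of
#' its correlation peaks (SE-level presence: duplicated peaks do not change
#' the count). The focal lncRNA's percentile is computed among lncRNAs with
#' count >= 1 as `100 * mean(count <= focal count)` ("le", default) or with
#' strict `<` ("lt").
#'
#' @param all_corr_peaks correlation peak data.frame over all lncRNAs
#' @param ses consensus SE data.frame
#' @param focal focal lncRNA id (must be present in the table)
#' @param tie_rule "le" (default) or "lt"
#' @return list: `counts` (lncrna_id, n_ses), `focal_count`,
#'   `n_with_overlap`, `percentile`
#' @export
lncrna_se_ranking <- function(all_corr_peaks, ses, focal,
                              tie_rule = c("le", "lt")) {
  tie_rule <- match.arg(tie_rule)
  validate_correlation_peaks(all_corr_peaks)
  if (!focal %in% all_corr_peaks$lncrna_id) {
    stop(sprintf("focal lncRNA '%s' absent from the correlation peak table", focal))
  }
  hits <- GenomicRanges::findOverlaps(bed_to_gr(ses), bed_to_gr(all_corr_peaks))
  pres <- unique(data.frame(
    se_id = ses$se_id[S4Vectors::queryHits(hits)],
    lncrna_id = all_corr_peaks$lncrna_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  all_ids <- unique(all_corr_peaks$lncrna_id)
  tab <- table(factor(pres$lncrna_id, levels = all_ids))
  counts <- data.frame(lncrna_id = all_ids, n_ses = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_ses, counts$lncrna_id, method = "radix"), ]
  rownames(counts) <- NULL
  focal_count <- counts$n_ses[counts$lncrna_id == focal]
  with_overlap <- counts$n_ses[counts$n_ses >= 1]
  percentile <- if (length(with_overlap) == 0) {
    NA_real_
  } else if (tie_rule == "le") {
    100 * mean(with_overlap <= focal_count)
  } else {
    100 * mean(with_overlap < focal_count)
  }
  list(counts = counts, focal_count = focal_count,
       n_with_overlap = length(with_overlap), percentile = percentile)
}
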