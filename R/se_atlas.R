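#' Per-sample super-enhancer annotation
#'
#' @param sample_id sample identifier
#' @param condition "cancer" or "normal"
#' @param ses interval data.frame of SE calls for this sample
#' @return an `se_sample` object
#' @export
se_sample <- function(sample_id, condition, ses) {
  condition <- match.arg(condition, c("cancer", "normal"))
  validate_intervals(ses)
  structure(list(sample_id = as.character(sample_id), condition = condition,
                 ses = iv_sort(ses)),
            class = "se_sample")
}

#' Build a per-condition consensus super-enhancer set
#'
#' Each sample's SE calls are first consolidated by merging intervals
#' separated by less than `intra_gap` bp (SE stitching). The union across
#' samples is then merged with `cross_gap` into candidate regions; a
#' candidate is retained iff at least `min_support` distinct samples
#' contribute >= 1 overlapping interval. Ids are assigned in genomic sort
#' order.
#'
#' @param samples list of [se_sample()] objects sharing one condition
#' @param min_support samples required per consensus SE
#' @param intra_gap within-sample merge distance (default 12,500 bp, strict <)
#' @param cross_gap cross-sample merge distance for candidate formation
#'   (default 0: touching/overlapping only)
#' @param id_prefix prefix for consensus SE ids (default "se_")
#' @return data.frame: se_id, chrom, start, end, condition, n_support
#' @export
build_condition_consensus <- function(samples, min_support,
                                      intra_gap = 12500, cross_gap = 0,
                                      id_prefix = "se_") {
  stopifnot(length(samples) >= 1)
  conds <- unique(vapply(samples, function(s) s$condition, character(1)))
  if (length(conds) != 1) {
    stop(sprintf("samples mix conditions: %s", paste(conds, collapse = ", ")))
  }
  if (min_support > length(samples)) {
    stop(sprintf("min_support (%d) exceeds number of samples (%d)",
                 min_support, length(samples)))
  }
  merged <- lapply(samples, function(s) iv_merge(s$ses, max_gap = intra_gap))
  pooled <- do.call(rbind, merged)
  if (nrow(pooled) == 0) {
    return(data.frame(se_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      condition = character(), n_support = integer(),
                      stringsAsFactors = FALSE))
  }
  cand <- iv_merge(pooled, max_gap = cross_gap)
  cand_gr <- bed_to_gr(cand)
  support <- rowSums(matrix(vapply(merged, function(m) {
    if (nrow(m) == 0) return(logical(length(cand_gr)))
    IRanges::overlapsAny(cand_gr, bed_to_gr(m))
  }, logical(length(cand_gr))), nrow = length(cand_gr)))
  keep <- cand[support >= min_support, , drop = FALSE]
  n_sup <- as.integer(support[support >= min_support])
  keep <- iv_sort(keep)
  data.frame(se_id = sprintf("%s%d", id_prefix, seq_len(nrow(keep))),
             chrom = keep$chrom, start = keep$start, end = keep$end,
             condition = rep(conds, nrow(keep)), n_support = n_sup,
             stringsAsFactors = FALSE)
}

#' Classify consensus SEs by tissue specificity
#'
#' A cancer SE overlapping any normal SE by at least `min_overlap_bp` is
#' "shared", otherwise "cancer-specific"; symmetrically for normal SEs.
#' For summary reporting a shared region is the merged union of its
#' overlapping cancer and normal consensus intervals, counted once.
#'
#' @param cancer,normal consensus SE data.frames from
#'   [build_condition_consensus()]
#' @param min_overlap_bp minimum overlap to call "shared" (default 1)
#' @return list: `cancer` and `normal` with a `specificity` column, and
#'   `summary` (n_cancer_specific, n_normal_specific, n_shared, n_total)
#' @export
classify_specificity <- function(cancer, normal, min_overlap_bp = 1) {
  lab <- function(a, b, specific_label) {
    if (nrow(a) == 0) {
      a$specificity <- character(0)
      return(a)
    }
    shared <- if (nrow(b) == 0) {
      logical(nrow(a))
    } else {
      IRanges::overlapsAny(bed_to_gr(a), bed_to_gr(b),
                           minoverlap = as.integer(min_overlap_bp))
    }
    a$specificity <- ifelse(shared, "shared", specific_label)
    a
  }
  cancer <- lab(cancer, normal, "cancer-specific")
  normal <- lab(normal, cancer, "normal-specific")
  shared_pool <- rbind(
    cancer[cancer$specificity == "shared", c("chrom", "start", "end")],
    normal[normal$specificity == "shared", c("chrom", "start", "end")])
  n_shared <- if (nrow(shared_pool) == 0) 0L else nrow(iv_merge(shared_pool, 0))
  summary <- data.frame(
    n_cancer_specific = sum(cancer$specificity == "cancer-specific"),
    n_normal_specific = sum(normal$specificity == "normal-specific"),
    n_shared = n_shared)
  summary$n_total <- summary$n_cancer_specific + summary$n_normal_specific +
    summary$n_shared
  list(cancer = cancer, normal = normal, summary = summary)
}

#' Read an SE sample manifest
#'
#' Headered TSV with columns `sample`, `condition`, `path` (BED files,
#' relative to the manifest directory unless absolute).
#'
#' @param manifest_path manifest TSV path
#' @return list of [se_sample()] objects
#' @export
read_se_manifest <- function(manifest_path) {
  man <- read_tsv_table(manifest_path)
  stopifnot(all(c("sample", "condition", "path") %in% names(man)))
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(k) {
    p <- man$path[k]
    if (!file.exists(p)) p <- file.path(base, man$path[k])
    se_sample(man$sample[k], man$condition[k], read_bed(p))
  })
}
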