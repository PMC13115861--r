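#' Per-fraction peak set of one biological replicate
#'
#' Split-probe RNA-chromatin capture assigns contacts to "odd" and "even"
#' probe fractions; a peak reproduced in both fractions is considered
#' probe-independent. The matched "input" fraction is carried only as
#' provenance (peak calling against it happens upstream of this package).
#'
#' @param replicate replicate identifier
#' @param fraction one of "odd", "even", "input"
#' @param peaks interval data.frame (narrowPeak payload allowed)
#' @return a `fraction_peaks` object
#' @export
fraction_peaks <- function(replicate, fraction, peaks) {
  fraction <- match.arg(fraction, c("odd", "even", "input"))
  validate_intervals(peaks)
  structure(list(replicate = as.character(replicate), fraction = fraction,
                 peaks = iv_sort(peaks)),
            class = "fraction_peaks")
}

#' Reconcile the odd and even fractions of one replicate
#'
#' Both fraction peak sets are symmetrically extended by `pad` bp; every
#' odd/even pair whose extended forms overlap by >= 1 bp yields one
#' replicate-supported interval. In the default `"union"` mode that interval
#' is the union of the two original peaks. In `"literal"` mode it is
#' `[min(starts) + pad, max(ends) - pad)` computed from the original
#' coordinates; degenerate results (end <= start) are dropped with a
#' warning. Supported intervals are merged (gap 0) within the replicate;
#' peaks with no cross-fraction partner are dropped.
#'
#' @param odd,even `fraction_peaks` objects from the same replicate
#' @param sizes named chromosome lengths
#' @param pad symmetric extension in bp (default 250)
#' @param mode "union" (default) or "literal"
#' @return a list with `replicate` and merged `peaks`
#' @export
reconcile_fractions <- function(odd, even, sizes, pad = 250,
                                mode = c("union", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(odd, "fraction_peaks"), inherits(even, "fraction_peaks"))
  if (odd$replicate != even$replicate) {
    stop(sprintf("fraction peak sets belong to different replicates ('%s' vs '%s')",
                 odd$replicate, even$replicate))
  }
  if (odd$fraction == even$fraction) {
    stop("reconcile_fractions needs one odd and one even fraction")
  }
  po <- odd$peaks; pe <- even$peaks
  if (nrow(po) == 0 || nrow(pe) == 0) {
    return(list(replicate = odd$replicate, peaks = empty_intervals()))
  }
  eo <- iv_slop(po, pad, sizes)
  ee <- iv_slop(pe, pad, sizes)
  hits <- GenomicRanges::findOverlaps(bed_to_gr(eo), bed_to_gr(ee))
  if (length(hits) == 0) {
    return(list(replicate = odd$replicate, peaks = empty_intervals()))
  }
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  lo <- pmin(po$start[i], pe$start[j])
  hi <- pmax(po$end[i], pe$end[j])
  if (mode == "literal") {
    lo <- lo + pad
    hi <- hi - pad
    keep <- hi > lo
    if (any(!keep)) {
      warning(sprintf(
        "%d reconstructed interval(s) degenerate under literal mode; dropped",
        sum(!keep)))
    }
    lo <- lo[keep]; hi <- hi[keep]; i <- i[keep]
  }
  if (length(lo) == 0) {
    return(list(replicate = odd$replicate, peaks = empty_intervals()))
  }
  rec <- data.frame(chrom = po$chrom[i], start = lo, end = hi,
                    stringsAsFactors = FALSE)
  list(replicate = odd$replicate, peaks = iv_merge(rec, max_gap = 0))
}

#' Consensus contact peaks across replicates
#'
#' A replicate-level interval is retained iff it overlaps (>= 1 bp) a
#' replicate-level interval from at least `min_support - 1` other
#' replicates. Retained intervals are pooled and merged (gap 0); each
#' consensus peak records how many replicates contribute an overlapping
#' interval.
#'
#' @param reps list of replicate peak sets as returned by
#'   [reconcile_fractions()]
#' @param min_support minimum number of supporting replicates (default 2)
#' @return interval data.frame of consensus peaks with columns `name`
#'   (peak id) and `n_support`
#' @export
replicate_consensus <- function(reps, min_support = 2) {
  stopifnot(length(reps) >= 1)
  if (min_support > length(reps)) {
    stop(sprintf("min_support (%d) exceeds number of replicates (%d)",
                 min_support, length(reps)))
  }
  peak_sets <- lapply(reps, function(r) r$peaks)
  grs <- lapply(peak_sets, function(p) {
    if (nrow(p) == 0) GenomicRanges::GRanges() else bed_to_gr(p)
  })
  kept <- vector("list", length(reps))
  for (r in seq_along(reps)) {
    p <- peak_sets[[r]]
    if (nrow(p) == 0) {
      kept[[r]] <- empty_intervals()
      next
    }
    others <- vapply(seq_along(reps)[-r], function(s) {
      IRanges::overlapsAny(grs[[r]], grs[[s]])
    }, logical(length(grs[[r]])))
    support <- 1L + rowSums(matrix(others, nrow = length(grs[[r]])))
    kept[[r]] <- p[support >= min_support, c("chrom", "start", "end"),
                   drop = FALSE]
  }
  pooled <- do.call(rbind, kept)
  if (is.null(pooled) || nrow(pooled) == 0) {
    out <- empty_intervals()
    out$name <- character(0)
    out$n_support <- integer(0)
    return(out)
  }
  cons <- iv_merge(pooled, max_gap = 0)
  cons_gr <- bed_to_gr(cons)
  n_support <- rowSums(matrix(vapply(grs, function(g) {
    IRanges::overlapsAny(cons_gr, g)
  }, logical(length(cons_gr))), nrow = length(cons_gr)))
  cons$name <- sprintf("contact_%d", seq_len(nrow(cons)))
  cons$n_support <- as.integer(n_support)
  cons
}

#' Read a fraction manifest and build per-replicate fraction sets
#'
#' The manifest is a headered TSV with columns `replicate`, `fraction`,
#' `path` (paths relative to the manifest's directory unless absolute).
#'
#' @param manifest_path manifest TSV path
#' @return named list: for each replicate, a list with `odd`, `even` and
#'   (optionally) `input` `fraction_peaks`
#' @export
read_fraction_manifest <- function(manifest_path) {
  man <- read_tsv_table(manifest_path)
  stopifnot(all(c("replicate", "fraction", "path") %in% names(man)))
  base <- dirname(manifest_path)
  out <- list()
  for (k in seq_len(nrow(man))) {
    p <- man$path[k]
    if (!file.exists(p)) p <- file.path(base, man$path[k])
    peaks <- if (grepl("narrowPeak$", p)) read_narrowpeak(p) else read_bed(p)
    rep_id <- as.character(man$replicate[k])
    out[[rep_id]][[man$fraction[k]]] <-
      fraction_peaks(rep_id, man$fraction[k], peaks)
  }
  out
}

#' Full contact-consensus stage: fractions to consensus peaks
#'
#' Optionally blacklist-filters every fraction first (whole-record removal),
#' reconciles odd/even per replicate, then applies the cross-replicate
#' support rule.
#'
#' @param fractions output of [read_fraction_manifest()], or an equivalently
#'   shaped list
#' @param sizes named chromosome lengths
#' @param pad odd/even reconciliation extension (default 250 bp)
#' @param min_support replicates required per consensus peak (default 2)
#' @param blacklist optional interval data.frame of excluded regions
#' @param mode reconciliation mode, see [reconcile_fractions()]
#' @return consensus peaks as from [replicate_consensus()]
#' @export
contact_consensus <- function(fractions, sizes, pad = 250, min_support = 2,
                              blacklist = NULL, mode = "union") {
  reps <- lapply(fractions, function(fr) {
    odd <- fr$odd; even <- fr$even
    if (is.null(odd) || is.null(even)) {
      stop("each replicate needs both an odd and an even fraction")
    }
    if (!is.null(blacklist)) {
      odd$peaks <- iv_subtract_filter(odd$peaks, blacklist)
      even$peaks <- iv_subtract_filter(even$peaks, blacklist)
    }
    reconcile_fractions(odd, even, sizes, pad = pad, mode = mode)
  })
  replicate_consensus(reps, min_support = min_support)
}
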