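#' Interval sets in BED convention
#'
#' Throughout the package genomic intervals are plain data.frames with columns
#' `chrom`, `start`, `end` in 0-based half-open (BED) coordinates, plus any
#' payload columns (name, score, sample id ...). Overlap means the half-open
#' ranges share at least one base; touching intervals do not overlap. Strand
#' is never used in interval arithmetic.
#'
#' @name intervals
NULL

#' Construct an interval data.frame
#'
#' @param chrom character vector of chromosome names
#' @param start 0-based inclusive starts (bp)
#' @param end 0-based exclusive ends (bp)
#' @param ... further payload columns
#' @return a validated data.frame with columns chrom, start, end, ...
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(), ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate an interval data.frame
#'
#' Checks the BED invariants (start >= 0, end > start, non-empty chrom) and,
#' when `sizes` is supplied, that every interval lies within its chromosome.
#' Errors name the first offending record.
#'
#' @param x interval data.frame
#' @param sizes optional chrom sizes (named numeric vector, see
#'   [read_chrom_sizes()])
#' @return x, invisibly
#' @export
validate_intervals <- function(x, sizes = NULL) {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop("interval set must be a data.frame with columns chrom, start, end")
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(is.na(x$chrom) | x$chrom == "" |
               is.na(x$start) | is.na(x$end) |
               x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf("invalid interval record %d: %s:%s-%s",
                 i, x$chrom[i], format(x$start[i]), format(x$end[i])))
  }
  if (!is.null(sizes)) {
    missing_chr <- setdiff(unique(x$chrom), names(sizes))
    if (length(missing_chr) > 0) {
      stop(sprintf("chromosome '%s' absent from chrom sizes", missing_chr[1]))
    }
    over <- which(x$end > sizes[x$chrom])
    if (length(over) > 0) {
      i <- over[1]
      stop(sprintf("interval record %d (%s:%s-%s) exceeds chromosome length %s",
                   i, x$chrom[i], format(x$start[i]), format(x$end[i]),
                   format(sizes[[x$chrom[i]]])))
    }
  }
  invisible(x)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

# BED (0-based half-open) <-> GRanges (1-based closed) conversion. All overlap
# machinery is delegated to GenomicRanges through these two helpers.
bed_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

gr_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Sort intervals by (chrom, start, end)
#'
#' Chromosomes sort lexicographically in the C locale.
#'
#' @param x interval data.frame
#' @return sorted data.frame (payload preserved)
#' @export
iv_sort <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x)
  o <- order(x$chrom, x$start, x$end, method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping or nearby intervals
#'
#' Two intervals on the same chromosome end up in one output interval when
#' they overlap, touch, or are separated by a gap strictly less than
#' `max_gap` bp. `max_gap = 0` merges only touching/overlapping intervals.
#' Payload columns are dropped (a merged interval has no single source
#' record).
#'
#' @param x interval data.frame
#' @param max_gap non-negative merge distance in bp (strict: gap < max_gap)
#' @return sorted, non-overlapping interval data.frame
#' @export
iv_merge <- function(x, max_gap = 0) {
  validate_intervals(x)
  stopifnot(max_gap >= 0)
  if (nrow(x) == 0) return(empty_intervals())
  gr <- GenomicRanges::reduce(bed_to_gr(x),
                              min.gapwidth = max(as.integer(max_gap), 1L))
  iv_sort(gr_to_bed(gr))
}

#' Keep intervals of `a` overlapping `b` (report-once)
#'
#' Each `a` interval is kept, with original coordinates and payload, iff it
#' overlaps at least one `b` interval by >= 1 bp (bedtools `intersect -u`
#' semantics). Half-open touching does not count as overlap.
#'
#' @param a,b interval data.frames
#' @return subset of `a`
#' @export
iv_intersect_keep <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) return(a[integer(0), , drop = FALSE])
  hit <- IRanges::overlapsAny(bed_to_gr(a), bed_to_gr(b))
  out <- a[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove intervals of `a` overlapping `b` (whole-record filter)
#'
#' Keeps `a` intervals with zero overlap against `b` (bedtools
#' `intersect -v` semantics: whole records are removed, never clipped).
#'
#' @param a,b interval data.frames
#' @return subset of `a` disjoint from `b`
#' @export
iv_subtract_filter <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    rownames(a) <- NULL
    return(a)
  }
  hit <- IRanges::overlapsAny(bed_to_gr(a), bed_to_gr(b))
  out <- a[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Symmetrically extend intervals, clamped to chromosome bounds
#'
#' Each interval becomes `[max(0, start - pad), min(chromlen, end + pad))`;
#' record order and payload are preserved.
#'
#' @param x interval data.frame
#' @param pad non-negative extension in bp
#' @param sizes named numeric vector of chromosome lengths
#' @return extended interval data.frame
#' @export
iv_slop <- function(x, pad, sizes) {
  validate_intervals(x, sizes = sizes)
  stopifnot(pad >= 0)
  if (nrow(x) == 0) return(x)
  out <- x
  out$start <- pmax(0, x$start - pad)
  out$end <- pmin(unname(sizes[x$chrom]), x$end + pad)
  out
}

#' Count overlapping intervals of `b` for each interval of `a`
#'
#' @param a,b interval data.frames
#' @return integer vector, one count per row of `a`
#' @export
iv_count_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0) return(integer(0))
  if (nrow(b) == 0) return(integer(nrow(a)))
  GenomicRanges::countOverlaps(bed_to_gr(a), bed_to_gr(b))
}

#' Randomly reposition intervals, preserving chromosome and length
#'
#' Each interval is placed uniformly at random on its own chromosome such
#' that placed intervals never overlap one another (they may touch),
#' emulating `bedtools shuffle -chrom -noOverlapping`. Placement is sampled
#' exactly uniformly over all feasible non-overlapping integer
#' configurations via the gap-composition construction, so no rejection is
#' needed unless an exclusion set is supplied. The same seed always yields
#' the same output.
#'
#' @param x interval data.frame (payload preserved, rows reordered)
#' @param sizes named numeric vector of chromosome lengths
#' @param seed integer seed
#' @param exclude optional interval data.frame; placements overlapping it are
#'   rejected and redrawn (bounded retries)
#' @param max_retries retry budget per chromosome when `exclude` is given
#' @return shuffled interval data.frame, sorted
#' @export
iv_shuffle <- function(x, sizes, seed, exclude = NULL, max_retries = 1000) {
  validate_intervals(x, sizes = sizes)
  if (!is.null(exclude)) validate_intervals(exclude)
  if (nrow(x) == 0) return(x)
  with_seed(seed, {
    parts <- split(seq_len(nrow(x)), x$chrom)
    placed <- lapply(names(parts), function(chr) {
      idx <- parts[[chr]]
      lens <- x$end[idx] - x$start[idx]
      clen <- sizes[[chr]]
      excl_gr <- NULL
      if (!is.null(exclude)) {
        exc <- exclude[exclude$chrom == chr, , drop = FALSE]
        if (nrow(exc) > 0) excl_gr <- bed_to_gr(exc)
      }
      for (try in seq_len(max_retries)) {
        pl <- place_nonoverlapping(lens, clen, chr)
        df <- data.frame(chrom = chr, start = pl$starts,
                         end = pl$starts + lens[pl$ord],
                         stringsAsFactors = FALSE)
        payload <- x[idx[pl$ord], setdiff(names(x), c("chrom", "start", "end")),
                     drop = FALSE]
        if (ncol(payload) > 0) df <- cbind(df, payload)
        if (is.null(excl_gr) || !any(IRanges::overlapsAny(bed_to_gr(df), excl_gr))) {
          return(df)
        }
      }
      stop(sprintf(
        "could not place shuffled intervals on %s within %d retries (exclusion too dense?)",
        chr, max_retries))
    })
    iv_sort(do.call(rbind, placed))
  })
}

# Core placement: uniform draw over all non-overlapping integer
# configurations of intervals with the given lengths on one chromosome.
# The intervals are assigned a random order along the chromosome and the
# free space is distributed as sorted gaps drawn uniformly over integer
# compositions (stars and bars), so no rejection sampling is needed.
# Returns ascending starts and the interval order they correspond to.
place_nonoverlapping <- function(lens, clen, chrom_label = "?") {
  if (sum(lens) > clen) {
    stop(sprintf(
      "infeasible shuffle on %s: total interval length %s exceeds chromosome length %s",
      chrom_label, format(sum(lens)), format(clen)))
  }
  n <- length(lens)
  ord <- if (n > 1) sample.int(n) else 1L
  slack <- clen - sum(lens)
  # hash sampling avoids allocating a population-sized vector per draw
  draw <- if (n <= (slack + n) / 2) {
    sample.int(slack + n, n, useHash = TRUE)
  } else {
    sample.int(slack + n, n)
  }
  gaps <- sort(draw) - seq_len(n)  # n values in 0..slack, non-decreasing
  starts <- gaps + cumsum(c(0, lens[ord][-n]))
  list(starts = starts, ord = ord)
}

# Which of the half-open queries [qs, qe) overlap any of the subject
# intervals given by ascending starts `ps` and prefix-maximum ends `pme`?
# Plain-vector kernel for the permutation loops.
any_overlap_sweep <- function(qs, qe, ps, pme) {
  if (length(ps) == 0) return(logical(length(qs)))
  j <- findInterval(qe - 1, ps)   # number of subject starts < qe
  hit <- j >= 1
  hit[hit] <- pme[j[hit]] > qs[hit]
  hit
}
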