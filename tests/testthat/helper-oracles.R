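# Per-base occupancy-bitmap oracles for interval arithmetic on toy genomes.
# Deliberately naive: every operation is computed position-by-position, with
# no shared code with the package's interval module.

bitmap_from <- function(df, len) {
  bm <- logical(len)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) bm[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  bm
}

intervals_from_bitmap <- function(bm, chrom = "chr1") {
  r <- rle(bm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

# merge: occupy, then fill internal zero-runs strictly shorter than max_gap
# (touching runs are already contiguous in the bitmap)
bitmap_merge <- function(df, max_gap, len, chrom = "chr1") {
  bm <- bitmap_from(df, len)
  if (any(bm) && max_gap > 0) {
    r <- rle(bm)
    n <- length(r$values)
    occ <- which(r$values)
    if (length(occ) >= 2) {
      for (k in seq_len(n)) {
        if (!r$values[k] && k > min(occ) && k < max(occ) &&
            r$lengths[k] < max_gap) {
          r$values[k] <- TRUE
        }
      }
    }
    bm <- inverse.rle(r)
  }
  intervals_from_bitmap(bm, chrom)
}

bitmap_keep_overlapping <- function(a, b, len) {
  bmb <- bitmap_from(b, len)
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(bmb[(a$start[i] + 1):a$end[i]])
  }, logical(1))
  out <- a[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

bitmap_count_overlaps <- function(a, b, len) {
  vapply(seq_len(nrow(a)), function(i) {
    sum(vapply(seq_len(nrow(b)), function(j) {
      b$start[j] < a$end[i] && b$end[j] > a$start[i]
    }, logical(1)))
  }, integer(1))
}

random_interval_set <- function(n, len, wmax = 2000) {
  st <- sample.int(len - wmax, n, replace = TRUE) - 1
  w <- sample.int(wmax, n, replace = TRUE)
  iv_sort(data.frame(chrom = "chr1", start = st, end = pmin(st + w, len),
                     stringsAsFactors = FALSE))
}

# place a fixed-width interval set by the package shuffler so that observed
# and permuted data share the same (non-overlapping) placement distribution
null_interval_set <- function(n, w, sizes, seed) {
  ch <- rep(names(sizes), length.out = n)
  tmpl <- data.frame(chrom = ch, start = 0, end = w, stringsAsFactors = FALSE)
  tmpl$start <- stats::ave(seq_len(n), ch,
                           FUN = function(i) (seq_along(i) - 1) * (w + 10))
  tmpl$end <- tmpl$start + w
  iv_shuffle(iv_sort(tmpl), sizes, seed = seed)
}

expect_same_intervals <- function(a, b) {
  expect_equal(iv_sort(a[, c("chrom", "start", "end")]),
               iv_sort(b[, c("chrom", "start", "end")]))
}
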