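#' Empirical permutation p-value (add-one convention)
#'
#' `p = (k + 1) / (n + 1)` with `k` the number of null draws at or above the
#' observed statistic over `n` permutations. The add-one convention means a
#' statistic exceeding the whole null range at n = 1000 reports 0.001, never
#' an exact zero.
#'
#' @param observed observed statistic
#' @param null vector of null draws
#' @return p in (0, 1]
#' @export
empirical_p <- function(observed, null) {
  if (length(null) == 0) stop("null distribution is empty")
  (sum(null >= observed) + 1) / (length(null) + 1)
}

#' Display an empirical p-value at three decimals
#'
#' With `style = "bound"` and zero exceedances, the minimum achievable
#' p-value is rendered as an upper bound ("< 0.001" at n = 1000), matching
#' the usual reporting of permutation tests that saturate.
#'
#' @param observed observed statistic
#' @param null vector of null draws
#' @param style "numeric" (default) or "bound"
#' @return character p-value
#' @export
format_empirical_p <- function(observed, null, style = c("numeric", "bound")) {
  style <- match.arg(style)
  k <- sum(null >= observed)
  p <- empirical_p(observed, null)
  if (style == "bound" && k == 0) {
    sprintf("< %.3f", round_half_up(p, 3))
  } else {
    sprintf("%.3f", round_half_up(p, 3))
  }
}

#' Fold enrichment over a permutation null
#'
#' @param observed observed statistic
#' @param null_mean mean of the null distribution (must be positive)
#' @return observed / null_mean (reported at two decimals in summaries)
#' @export
fold_enrichment <- function(observed, null_mean) {
  if (!is.finite(null_mean) || null_mean <= 0) {
    stop("null mean must be positive for a fold enrichment")
  }
  observed / null_mean
}

perm_result <- function(observed, null, n_iter, seed) {
  structure(list(observed = observed, null = null,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 null_range = range(null),
                 p = empirical_p(observed, null),
                 fold = if (mean(null) > 0) observed / mean(null) else NA_real_,
                 n_iter = n_iter, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed %s vs null %.1f +/- %.1f (range %s-%s)\n  p = %s, fold enrichment = %.2f (%d iterations, seed %d)\n",
    format(x$observed), x$null_mean, x$null_sd,
    format(x$null_range[1]), format(x$null_range[2]),
    format_empirical_p(x$observed, x$null), round_half_up(x$fold, 2),
    x$n_iter, x$seed))
  invisible(x)
}

#' Genome-shuffle overlap enrichment test
#'
#' Observed statistic: number of target intervals overlapped by >= 1 peak.
#' Each iteration repositions the peaks with [iv_shuffle()]
#' (chromosome-preserving, non-overlapping, seeded per-iteration
#' substreams) and recounts. Deterministic for a fixed seed.
#'
#' @param targets interval data.frame (e.g. cancer-specific SEs)
#' @param peaks interval data.frame to shuffle (e.g. contact peaks)
#' @param sizes named chromosome lengths
#' @param seed integer seed
#' @param n_iter permutations (default 1000)
#' @param exclude optional exclusion set passed to [iv_shuffle()]
#' @return a `perm_result`
#' @export
permute_overlap_enrichment <- function(targets, peaks, sizes, seed,
                                       n_iter = 1000, exclude = NULL) {
  validate_intervals(targets)
  validate_intervals(peaks, sizes = sizes)
  observed <- sum(IRanges::overlapsAny(bed_to_gr(targets), bed_to_gr(peaks)))
  seeds <- iteration_seeds(seed, n_iter)
  if (is.null(exclude)) {
    chroms <- sort(unique(peaks$chrom))
    lens <- lapply(chroms, function(ch) {
      k <- peaks$chrom == ch
      peaks$end[k] - peaks$start[k]
    })
    tgt <- lapply(chroms, function(ch) {
      k <- targets$chrom == ch
      list(s = targets$start[k], e = targets$end[k])
    })
    null <- vapply(seeds, function(s) {
      with_seed(s, {
        tot <- 0
        for (ci in seq_along(chroms)) {
          if (length(tgt[[ci]]$s) == 0) {
            place_nonoverlapping(lens[[ci]], sizes[[chroms[ci]]], chroms[ci])
            next
          }
          pl <- place_nonoverlapping(lens[[ci]], sizes[[chroms[ci]]], chroms[ci])
          pme <- cummax(pl$starts + lens[[ci]][pl$ord])
          tot <- tot + sum(any_overlap_sweep(tgt[[ci]]$s, tgt[[ci]]$e,
                                             pl$starts, pme))
        }
        tot
      })
    }, numeric(1))
  } else {
    tgt_gr <- bed_to_gr(targets)
    null <- vapply(seeds, function(s) {
      shuf <- iv_shuffle(peaks, sizes, seed = s, exclude = exclude)
      sum(IRanges::overlapsAny(tgt_gr, bed_to_gr(shuf)))
    }, numeric(1))
  }
  perm_result(observed, null, n_iter, seed)
}

#' Joint two-layer (triple-intersection) enrichment test
#'
#' Observed statistic: number of SEs carrying >= 1 contact-confirmed
#' correlation peak. Each iteration shuffles the CONTACT peaks only,
#' re-derives the iteration-specific confirmed correlation peaks, and
#' recounts the SEs containing at least one of them.
#'
#' @param ses consensus SE data.frame
#' @param corr_peaks correlation peaks of the focal lncRNA
#' @param contacts consensus contact peak data.frame
#' @param sizes named chromosome lengths
#' @param seed integer seed
#' @param n_iter permutations (default 1000)
#' @param exclude optional exclusion set passed to [iv_shuffle()]
#' @return a `perm_result`
#' @export
permute_triple_enrichment <- function(ses, corr_peaks, contacts, sizes, seed,
                                      n_iter = 1000, exclude = NULL) {
  validate_intervals(ses)
  validate_intervals(corr_peaks)
  validate_intervals(contacts, sizes = sizes)
  se_gr <- bed_to_gr(ses)
  corr_gr <- bed_to_gr(corr_peaks)
  count_confirmed_ses <- function(contact_gr) {
    if (length(corr_gr) == 0) return(0)
    conf <- corr_gr[IRanges::overlapsAny(corr_gr, contact_gr)]
    if (length(conf) == 0) return(0)
    sum(IRanges::overlapsAny(se_gr, conf))
  }
  observed <- count_confirmed_ses(bed_to_gr(contacts))
  seeds <- iteration_seeds(seed, n_iter)
  if (is.null(exclude) && nrow(corr_peaks) > 0) {
    # SE x correlation-peak incidence is fixed across iterations; only the
    # confirmation state of each correlation peak changes with the shuffle
    inc <- GenomicRanges::findOverlaps(se_gr, corr_gr)
    inc_se <- S4Vectors::queryHits(inc)
    inc_corr <- S4Vectors::subjectHits(inc)
    chroms <- sort(unique(contacts$chrom))
    lens <- lapply(chroms, function(ch) {
      k <- contacts$chrom == ch
      contacts$end[k] - contacts$start[k]
    })
    crr <- lapply(chroms, function(ch) {
      k <- which(corr_peaks$chrom == ch)
      list(idx = k, s = corr_peaks$start[k], e = corr_peaks$end[k])
    })
    null <- vapply(seeds, function(s) {
      with_seed(s, {
        conf <- logical(nrow(corr_peaks))
        for (ci in seq_along(chroms)) {
          pl <- place_nonoverlapping(lens[[ci]], sizes[[chroms[ci]]],
                                     chroms[ci])
          if (length(crr[[ci]]$idx) == 0) next
          pme <- cummax(pl$starts + lens[[ci]][pl$ord])
          conf[crr[[ci]]$idx] <- any_overlap_sweep(crr[[ci]]$s, crr[[ci]]$e,
                                                   pl$starts, pme)
        }
        length(unique(inc_se[conf[inc_corr]]))
      })
    }, numeric(1))
  } else {
    null <- vapply(seeds, function(s) {
      shuf <- iv_shuffle(contacts, sizes, seed = s, exclude = exclude)
      count_confirmed_ses(bed_to_gr(shuf))
    }, numeric(1))
  }
  perm_result(observed, null, n_iter, seed)
}

#' One-sided Mann-Whitney U test (x stochastically greater)
#'
#' Ties are handled by mid-ranks. For `length(x) + length(y) <= 12` (or
#' `exact = TRUE`) the p-value is computed by exhaustive enumeration of all
#' group assignments of the pooled values; otherwise by the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors of counts
#' @param exact force (TRUE) or forbid (FALSE) enumeration; default NULL
#'   picks enumeration iff the pooled size is <= 12
#' @return list: U statistic, p, method
#' @export
mann_whitney_one_sided <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (is.null(exact)) exact <- N <= 12
  if (exact) {
    combos <- utils::combn(N, m)
    U_perm <- apply(combos, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
    p <- mean(U_perm >= U - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(m * n / 12 * ((N + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5) / sigma
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(U = U, p = p, method = method)
}
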