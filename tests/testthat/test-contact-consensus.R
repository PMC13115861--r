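sizes10 <- c(chr1 = 1e6)

fp <- function(rep, frac, chrom, start, end) {
  fraction_peaks(rep, frac, data.frame(chrom = chrom, start = start,
                                       end = end, stringsAsFactors = FALSE))
}

test_that("odd/even reconciliation follows the pad-overlap rule", {
  # gap 100: +/-250 bp extensions overlap -> union of the originals
  r <- reconcile_fractions(fp("r1", "odd", "chr1", 1000, 1500),
                           fp("r1", "even", "chr1", 1600, 2000), sizes10)
  expect_equal(r$peaks, intervals("chr1", 1000, 2000))
  # gap 500: extensions touch at a half-open boundary -> dropped
  r2 <- reconcile_fractions(fp("r1", "odd", "chr1", 1000, 1500),
                            fp("r1", "even", "chr1", 2000, 2500), sizes10)
  expect_equal(nrow(r2$peaks), 0)
  # gap 499 is the last surviving separation
  r3 <- reconcile_fractions(fp("r1", "odd", "chr1", 1000, 1500),
                            fp("r1", "even", "chr1", 1999, 2500), sizes10)
  expect_equal(r3$peaks, intervals("chr1", 1000, 2500))
  expect_error(reconcile_fractions(fp("r1", "odd", "chr1", 0, 10),
                                   fp("r2", "even", "chr1", 0, 10), sizes10),
               "different replicates")
})

test_that("literal mode shrinks pairs and drops degenerate reconstructions", {
  # overlapping short pair: literal [min+250, max-250) inverts -> dropped
  expect_warning(
    r <- reconcile_fractions(fp("r1", "odd", "chr1", 1000, 1300),
                             fp("r1", "even", "chr1", 1100, 1400), sizes10,
                             mode = "literal"),
    "degenerate")
  expect_equal(nrow(r$peaks), 0)
  # long pair survives, shrunk by pad on each side
  r2 <- reconcile_fractions(fp("r1", "odd", "chr1", 1000, 3000),
                            fp("r1", "even", "chr1", 1200, 3200), sizes10,
                            mode = "literal")
  expect_equal(r2$peaks, intervals("chr1", 1250, 2950))
  # literal output is always contained in the union-mode output
  withr::with_seed(4, {
    for (i in 1:10) {
      o <- random_interval_set(15, 50000, wmax = 600)
      e <- random_interval_set(15, 50000, wmax = 600)
      u <- reconcile_fractions(fp("r", "odd", o$chrom, o$start, o$end),
                               fp("r", "even", e$chrom, e$start, e$end),
                               sizes10)$peaks
      l <- suppressWarnings(
        reconcile_fractions(fp("r", "odd", o$chrom, o$start, o$end),
                            fp("r", "even", e$chrom, e$start, e$end),
                            sizes10, mode = "literal")$peaks)
      if (nrow(l) > 0) {
        expect_equal(nrow(iv_intersect_keep(l, u)), nrow(l))
        expect_equal(nrow(iv_subtract_filter(l, u)), 0)
      }
    }
  })
})

test_that("union-mode reconciliation matches a brute-force pairwise oracle", {
  withr::with_seed(2026, {
    for (i in 1:15) {
      o <- random_interval_set(sample(3:20, 1), 80000, wmax = 800)
      e <- random_interval_set(sample(3:20, 1), 80000, wmax = 800)
      got <- reconcile_fractions(fp("r", "odd", o$chrom, o$start, o$end),
                                 fp("r", "even", e$chrom, e$start, e$end),
                                 sizes10, pad = 250)$peaks
      # oracle: test every odd/even pair by direct arithmetic
      pieces <- list()
      for (a in seq_len(nrow(o))) {
        for (b in seq_len(nrow(e))) {
          if (o$start[a] - 250 < e$end[b] + 250 &&
              e$start[b] - 250 < o$end[a] + 250) {
            pieces[[length(pieces) + 1]] <-
              data.frame(chrom = "chr1",
                         start = min(o$start[a], e$start[b]),
                         end = max(o$end[a], e$end[b]))
          }
        }
      }
      want <- if (length(pieces) == 0) intervals() else
        iv_merge(do.call(rbind, pieces), 0)
      expect_equal(got, want)
    }
  })
})

test_that("one odd peak pairing with two even peaks yields both unions", {
  r <- reconcile_fractions(
    fp("r1", "odd", "chr1", 5000, 5400),
    fp("r1", "even", c("chr1", "chr1"), c(4600, 5500), c(4900, 5900)),
    sizes10)
  # both reconstructed unions overlap each other -> merged into one
  expect_equal(r$peaks, intervals("chr1", 4600, 5900))
})

test_that("the >= 2-of-3 replicate support rule is enforced", {
  reps <- list(
    list(replicate = "r1", peaks = intervals(c("chr1", "chr1"), c(100, 5000),
                                             c(400, 5300))),
    list(replicate = "r2", peaks = intervals("chr1", 150, 450)),
    list(replicate = "r3", peaks = intervals("chr1", 9000, 9300)))
  cons <- replicate_consensus(reps, min_support = 2)
  # shared peak kept (merged across r1/r2), private peaks dropped
  expect_equal(cons[, c("chrom", "start", "end")],
               intervals("chr1", 100, 450))
  expect_equal(cons$n_support, 2L)
  expect_error(replicate_consensus(reps, min_support = 4), "min_support")
  # output is invariant to replicate order
  cons2 <- replicate_consensus(rev(reps), min_support = 2)
  expect_equal(cons[, c("chrom", "start", "end", "n_support")],
               cons2[, c("chrom", "start", "end", "n_support")])
})

test_that("blacklisted artifacts vanish; without the blacklist they persist", {
  sim <- default_sim()
  with_bl <- contact_consensus(sim$inputs$fractions, sim$inputs$sizes,
                               blacklist = sim$inputs$blacklist)
  without <- contact_consensus(sim$inputs$fractions, sim$inputs$sizes)
  expect_equal(nrow(with_bl), sim$truth$n_contact_peaks)
  expect_equal(nrow(without),
               sim$truth$n_contact_peaks + sim$truth$n_artifact_peaks)
})

test_that("consensus recovers exactly the planted peaks", {
  sim <- default_sim()
  cons <- contact_consensus(sim$inputs$fractions, sim$inputs$sizes,
                            blacklist = sim$inputs$blacklist)
  expect_equal(nrow(cons), sim$truth$n_contact_peaks)
  # one-to-one: every consensus peak overlaps exactly one planted peak
  planted <- sim$truth$contact_intervals
  expect_equal(unname(iv_count_overlaps(cons, planted)), rep(1L, nrow(cons)))
  expect_equal(unname(iv_count_overlaps(planted, cons)), rep(1L, nrow(planted)))
  # a noise-free, jitter-free simulation reproduces coordinates exactly
  cfg0 <- simulation_config(seed = 7, noise_lambda = 0, contact_jitter = 0)
  sim0 <- simulate_study(cfg0)
  cons0 <- contact_consensus(sim0$inputs$fractions, sim0$inputs$sizes,
                             blacklist = sim0$inputs$blacklist)
  expect_equal(cons0[, c("chrom", "start", "end")],
               iv_sort(sim0$truth$contact_intervals))
})
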