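corr_df <- function(chrom, start, end, lnc = "lncA", mark = "H3K4me1",
                    sign = "+") {
  data.frame(chrom = chrom, start = start, end = end, lncrna_id = lnc,
             mark = mark, sign = sign, stringsAsFactors = FALSE)
}

ses_df <- function(id, chrom, start, end) {
  data.frame(se_id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("confirmation keeps exactly the contact-overlapping peaks", {
  contacts <- intervals("chr1", 1000, 1500)
  onpeak <- corr_df("chr1", 1400, 1700)
  offpeak <- corr_df("chr1", 5000, 5300)
  got <- confirm_peaks(rbind(onpeak, offpeak), contacts)
  expect_equal(got, onpeak)
  expect_equal(nrow(confirm_peaks(offpeak, contacts)), 0)
  # annotations and coordinates unchanged; subset and idempotent
  expect_equal(confirm_peaks(got, contacts), got)
  mixed <- rbind(onpeak, corr_df("chr1", 1, 10, lnc = "lncB"))
  expect_error(confirm_peaks(mixed, contacts), "lncRNA")
  bad <- corr_df("chr1", 1, 10, mark = "H3K9ac")
  expect_error(confirm_peaks(bad, contacts), "mark")
  neg <- corr_df("chr1", 1, 300)
  neg$rho <- -0.4
  expect_error(validate_correlation_peaks(neg), "sign/value")
})

test_that("psi/omega labels partition SEs and profiles track mark instances", {
  ses <- ses_df(c("se_1", "se_2", "se_3"), "chr1",
                c(10000, 50000, 90000), c(20000, 60000, 99000))
  confirmed <- rbind(
    corr_df("chr1", 11000, 11300),                      # se_1: H3K4me1 +
    corr_df("chr1", 12000, 12300),                      # se_1: same pair again
    corr_df("chr1", 13000, 13300, mark = "H3K4me3"),    # se_1: second instance
    corr_df("chr1", 51000, 51300, mark = "H3K4me3", sign = "-"))  # se_2
  cl <- classify_ses(ses, confirmed)
  expect_equal(cl$ses$psi, c("psi", "psi", "omega"))
  expect_equal(sort(unique(cl$ses$psi[cl$ses$n_confirmed_peaks > 0])), "psi")
  # distinct (mark, sign) pairs per SE; peak multiplicity reported apart
  p1 <- cl$profiles[cl$profiles$se_id == "se_1", ]
  expect_equal(nrow(p1), 2)
  expect_equal(p1$n_peaks[p1$mark == "H3K4me1"], 2L)
  expect_equal(cl$summary$n_mark_instances, 3)
  expect_equal(cl$summary$n_compound, 1)   # only se_1 has >= 2 instances
  # every omega SE has an empty profile
  expect_false("se_3" %in% cl$profiles$se_id)
  expect_equal(cl$summary$pct_psi, round(100 * 2 / 3, 1))
})

test_that("contact density counts per SE and matches naive counting", {
  ses <- ses_df(c("se_1", "se_2"), "chr1", c(1000, 3000), c(2000, 4000))
  contacts <- intervals(rep("chr1", 3), c(1100, 1500, 1900), c(1200, 1600, 3100))
  d <- contact_density(ses, contacts)
  expect_equal(d$n_contacts, c(3L, 1L))   # spanning peak counted in both
  withr::with_seed(12, {
    a <- random_interval_set(40, 50000, wmax = 3000)
    a$se_id <- sprintf("se_%d", seq_len(nrow(a)))
    b <- random_interval_set(60, 50000, wmax = 1000)
    expect_equal(contact_density(a, b)$n_contacts,
                 bitmap_count_overlaps(a, b, 50000))
  })
})

test_that("promoter-mode hits are recovered exactly on the synthetic atlas", {
  sim <- default_sim()
  rep <- default_report()
  hits <- rep$tss_mode$tss_hits
  expect_equal(hits[, c("se_id", "gene_id")], sim$truth$tss_mode)
  # the promoter-mode SEs are omega, not psi
  cls <- rep$classification$ses
  expect_true(all(cls$psi[cls$se_id %in% hits$se_id] == "omega"))
})

test_that("unknown gene strand falls back to the start coordinate", {
  ses <- ses_df("se_1", "chr1", 10000, 20000)
  ses$psi <- "omega"
  genes <- data.frame(gene_id = "G1", symbol = "G1", chrom = "chr1",
                      start = 50000, end = 55000, strand = ".",
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  targets <- data.frame(se_id = "se_1", gene_id = "G1",
                        stringsAsFactors = FALSE)
  confirmed <- corr_df("chr1", 49500, 49800)
  expect_warning(tm <- tss_mode(ses, confirmed, genes, targets,
                                promoter_pad = 2000), "strand")
  expect_equal(tm$tss_hits$gene_id, "G1")
})

test_that("lncRNA ranking counts SE presence and applies the tie rule", {
  ses <- ses_df(sprintf("se_%d", 1:3), "chr1",
                c(10000, 50000, 90000), c(20000, 60000, 99000))
  peaks <- rbind(
    corr_df("chr1", c(11000, 51000, 91000), c(11300, 51300, 91300), "top"),
    corr_df("chr1", c(11500, 51500), c(11800, 51800), "mid"),
    corr_df("chr1", 500000, 500300, "none"))
  r <- lncrna_se_ranking(peaks, ses, "top")
  expect_equal(r$focal_count, 3L)
  expect_equal(r$n_with_overlap, 2)   # "none" has zero SEs
  expect_equal(r$percentile, 100)
  # strictly largest -> 100 under both tie rules
  expect_equal(lncrna_se_ranking(peaks, ses, "top", tie_rule = "lt")$percentile,
               50)
  # all tied -> 100 under the <= convention
  tied <- rbind(corr_df("chr1", 11000, 11300, "a"),
                corr_df("chr1", 11500, 11800, "b"))
  expect_equal(lncrna_se_ranking(tied, ses, "a")$percentile, 100)
  # duplicating the peak table must not change counts or percentile
  r2 <- lncrna_se_ranking(rbind(peaks, peaks), ses, "top")
  expect_equal(r2$counts, r$counts)
  expect_equal(r2$percentile, r$percentile)
  expect_error(lncrna_se_ranking(peaks, ses, "absent"), "absent")
})

test_that("synthetic ranking matches a brute-force count-and-sort oracle", {
  sim <- default_sim()
  rep <- default_report()
  r <- rep$ranking
  truth_counts <- sim$truth$lnc_se_counts
  expect_equal(r$focal_count, unname(truth_counts[sim$inputs$focal_id]))
  # oracle: sort the planted counts, percentile of the focal among >= 1
  wo <- truth_counts[truth_counts >= 1]
  expect_equal(r$n_with_overlap, length(wo))
  expect_equal(r$percentile,
               100 * mean(wo <= truth_counts[sim$inputs$focal_id]))
  # per-lncRNA counts equal the planted counts
  got <- stats::setNames(r$counts$n_ses, r$counts$lncrna_id)
  expect_equal(got[names(truth_counts)], truth_counts)
})

test_that("psi count grows monotonically with the confirmed set", {
  ses <- ses_df(sprintf("se_%d", 1:5), "chr1", (1:5) * 50000,
                (1:5) * 50000 + 10000)
  all_conf <- corr_df("chr1", (1:4) * 50000 + 100, (1:4) * 50000 + 400)
  n_prev <- 0
  for (k in 0:4) {
    cl <- classify_ses(ses, all_conf[seq_len(k), , drop = FALSE])
    n <- sum(cl$ses$psi == "psi")
    expect_gte(n, n_prev)
    n_prev <- n
  }
  expect_equal(n_prev, 4)
})
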