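mk_genes <- function(start, end, tpm, strand = "+",
                     biotype = "protein_coding", chrom = "chr1") {
  n <- length(start)
  data.frame(gene_id = sprintf("G%02d", seq_len(n)),
             symbol = sprintf("S%02d", seq_len(n)),
             chrom = chrom, start = start, end = end,
             strand = rep_len(strand, n), biotype = rep_len(biotype, n),
             tpm_cancer = tpm, stringsAsFactors = FALSE)
}

one_se <- data.frame(se_id = "se_1", chrom = "chr1", start = 500000,
                     end = 540000, stringsAsFactors = FALSE)

test_that("association window and expression thresholds are literal", {
  genes <- mk_genes(
    start = c(640000,    # exactly 100 kb downstream of the SE end: kept
              640001,    # 100,001 bp: excluded
              400000,    # exactly 100 kb upstream of the SE start: kept
              510000,    # overlaps the SE: kept, distance 0
              515000,    # overlaps but TPM exactly 1: excluded (strict >)
              520000),   # overlaps but lncRNA biotype: excluded
    end = c(648000, 649000, 408000, 512000, 517000, 523000),
    tpm = c(5, 5, 5, 8, 1, 50),
    biotype = c(rep("protein_coding", 5), "lncRNA"))
  a <- assign_targets(one_se, genes, window = 100000, tpm_min = 1)
  expect_setequal(a$gene_id, c("G01", "G03", "G04"))
  expect_equal(a$distance[a$gene_id == "G01"], 100000)
  expect_equal(a$distance[a$gene_id == "G03"], 100000)
  expect_equal(a$distance[a$gene_id == "G04"], 0)
  # a gene body reaching into the window from beyond it does not qualify:
  # only the start coordinate is tested
  far <- mk_genes(start = 645000, end = 700000, tpm = 9)
  expect_equal(nrow(assign_targets(one_se, far)), 0)
})

test_that("shrinking the window or raising tpm_min never adds associations", {
  withr::with_seed(21, {
    genes <- mk_genes(start = sample.int(9e5, 60), end = 0, tpm = runif(60, 0, 8))
    genes$end <- genes$start + 5000
    prev <- Inf
    for (w in c(150000, 100000, 50000, 0)) {
      n <- nrow(assign_targets(one_se, genes, window = w))
      expect_lte(n, prev)
      prev <- n
    }
    prev <- Inf
    for (tm in c(0.5, 1, 2, 6)) {
      n <- nrow(assign_targets(one_se, genes, tpm_min = tm))
      expect_lte(n, prev)
      prev <- n
    }
  })
})

test_that("lead genes minimize padj with documented tie-breaking", {
  assocs <- data.frame(se_id = c("se_1", "se_1", "se_1", "se_2"),
                       gene_id = c("G01", "G02", "G03", "G04"),
                       symbol = c("A", "B", "C", "D"),
                       distance = 0, tpm = 5, stringsAsFactors = FALSE)
  de <- data.frame(gene_id = c("G01", "G02", "G03"),
                   log2FC = c(1.2, -3.5, 3.5), padj = c(0.2, 1e-5, 1e-5),
                   stringsAsFactors = FALSE)
  expect_warning(lg <- lead_gene(assocs, de), "padj = 1")
  # padj tie between G02/G03 broken by larger |log2FC| (equal) then gene id
  expect_equal(lg$leads$gene_id[lg$leads$se_id == "se_1"], "G02")
  expect_true(lg$leads$significant[lg$leads$se_id == "se_1"])
  # G04 missing from DE: padj 1, lead of its SE but non-significant
  expect_equal(lg$leads$gene_id[lg$leads$se_id == "se_2"], "G04")
  expect_false(lg$leads$significant[lg$leads$se_id == "se_2"])
  expect_equal(sum(lg$assocs$lead), 2)
  # an SE with no associations simply has no lead row
  expect_false("se_9" %in% lg$leads$se_id)
})

test_that("Welch DE matches the closed form and t.test", {
  x <- c(4.1, 5.3, 4.8); y <- c(2.0, 2.9, 2.2)
  m <- matrix(c(x, y), 1, dimnames = list("G1", NULL))
  de <- welch_de(m, c(rep("tumor", 3), rep("normal", 3)))
  v1 <- var(x); v0 <- var(y); se2 <- v1 / 3 + v0 / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((v1 / 3)^2 / 2 + (v0 / 3)^2 / 2)
  expect_equal(de$t, t_hand, tolerance = 1e-10)
  expect_equal(de$df, df_hand, tolerance = 1e-10)
  expect_equal(de$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  expect_equal(de$log2FC, mean(x) - mean(y))
  tt <- t.test(x, y)
  expect_equal(de$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(de$p, tt$p.value, tolerance = 1e-10)
  # zero variance in both groups: equal means -> t 0, p 1
  mz <- matrix(c(1, 1, 1, 1, 1, 1, 2, 2, 2, 1, 1, 1), 2, byrow = TRUE,
               dimnames = list(c("Ga", "Gb"), NULL))
  dez <- welch_de(mz, c(rep("tumor", 3), rep("normal", 3)))
  expect_equal(dez$t[1], 0); expect_equal(dez$p[1], 1)
  expect_equal(dez$p[2], 0)  # zero variance, different means
  expect_error(welch_de(m, c("tumor", rep("normal", 5))), ">= 2")
})

test_that("planted cohort shifts are estimated consistently", {
  withr::with_seed(30, {
    n <- 400; delta <- 1.3
    m <- rbind(shifted = c(rnorm(n, 5 + delta, 0.5), rnorm(n, 5, 0.5)),
               flat = c(rnorm(n, 4, 0.5), rnorm(n, 4, 0.5)))
    de <- welch_de(m, c(rep("tumor", n), rep("normal", n)))
    expect_lt(abs(de$log2FC[1] - delta), 0.15)
    expect_lt(de$padj[1], 1e-6)
    expect_gt(de$p[2], 0.001)
  })
})

test_that("triple validation demands all three concordant layers", {
  assocs <- data.frame(se_id = "se_13",
                       gene_id = c("CDC20", "DOWN", "NOCOR", "LOST"),
                       symbol = c("CDC20", "DOWN", "NOCOR", "LOST"),
                       distance = 0, tpm = 20, stringsAsFactors = FALSE)
  de_cell <- data.frame(gene_id = c("CDC20", "DOWN", "NOCOR"),
                        log2FC = c(1.76, -3.8, 2.0),
                        padj = c(0.01, 1e-30, 1e-4), stringsAsFactors = FALSE)
  de_cohort <- data.frame(gene_id = c("CDC20", "DOWN", "NOCOR", "LOST"),
                          log2FC = c(1.349, 1.0, 1.2, 1.5),
                          p = c(1e-6, 1e-4, 1e-5, 1e-8),
                          stringsAsFactors = FALSE)
  coexpr <- data.frame(gene_id = c("CDC20", "DOWN", "NOCOR", "LOST"),
                       rho = c(0.2226, 0.3, 0, 0.4),
                       p = c(1e-5, 1e-4, 0.9, 1e-6),
                       fdr = c(1e-4, 1e-3, 0.95, 1e-5),
                       stringsAsFactors = FALSE)
  expect_message(v <- triple_validate(assocs, de_cell, de_cohort, coexpr),
                 "not mappable")
  got <- stats::setNames(v$triple_validated, v$gene_id)
  expect_true(got[["CDC20"]])          # up + up + positively correlated
  expect_false(got[["DOWN"]])          # cell-line downregulation fails layer 1
  expect_false(got[["NOCOR"]])         # rho = 0 fails layer 3
  expect_false(got[["LOST"]])          # unmappable in the cell table
  expect_true(all(v$triple_validated ==
                    (v$cell_up & v$cohort_up & v$coexpr_pos)))
})
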