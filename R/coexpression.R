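all_permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- all_permutations(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

#' Spearman rank correlation with small-sample exact p
#'
#' Rho is the Pearson correlation of mid-ranks. The two-sided p-value is
#' computed by exhaustive enumeration over all n! permutations for n < 10
#' (counting permutations with |rho| at least as extreme), and by the
#' t-approximation with n - 2 df otherwise. Zero variance in either vector
#' gives an undefined rho (NA).
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param p_method "auto" (default: exact for n < 10), "exact" or "approx"
#' @return list: rho, p, n, method
#' @export
spearman_cor <- function(x, y, p_method = c("auto", "exact", "approx")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- switch(p_method, auto = n < 10, exact = TRUE, approx = FALSE)
  if (use_exact) {
    P <- all_permutations(seq_len(n))
    M <- matrix(ry[t(P)], nrow = n)  # column j = ry permuted by row j of P
    rho_perm <- drop(stats::cor(rx, M))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Purity-corrected partial Spearman correlation
#'
#' All three vectors are rank-transformed (mid-ranks); the ranks of x and y
#' are each linearly regressed on the ranks of z, and the Pearson
#' correlation of the two residual vectors is returned. Samples with a
#' missing value in any vector are dropped. Constant z degenerates to the
#' ordinary Spearman correlation exactly.
#'
#' @param x,y numeric vectors
#' @param z confounder (e.g. tumor purity)
#' @return partial rho
#' @export
partial_spearman <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  ok <- !(is.na(x) | is.na(y) | is.na(z))
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  if (length(x) < 3) stop("need at least 3 complete triples")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  vz <- stats::var(rz)
  if (vz == 0) return(stats::cor(rx, ry))
  bx <- stats::cov(rx, rz) / vz
  by <- stats::cov(ry, rz) / vz
  ex <- rx - mean(rx) - bx * (rz - mean(rz))
  ey <- ry - mean(ry) - by * (rz - mean(rz))
  stats::cor(ex, ey)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the single
#' FDR entry point of the package.
#'
#' @param p vector of p-values in [0, 1] (NA allowed)
#' @return FDR vector
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

# Residualize the rows of a rank matrix against a rank covariate (OLS).
residualize_ranks <- function(R, rz) {
  rzc <- rz - mean(rz)
  vz <- sum(rzc^2)
  if (vz == 0) return(R - rowMeans(R))
  b <- (R %*% rzc) / vz
  R - rowMeans(R) - b %*% rzc
}

#' Per-gene co-expression of a focal gene across a cohort
#'
#' Spearman rho of the focal gene against every other gene (t-approximation
#' p, BH FDR) and, when purity is supplied, the purity-corrected partial
#' Spearman restricted to samples with a purity value.
#'
#' @param expr genes x samples matrix (log2(TPM + 1))
#' @param focal focal gene row id
#' @param gene_ids genes to correlate (default: all rows except the focal)
#' @param purity optional per-sample purity vector aligned to columns (NA =
#'   unavailable); triggers the partial_rho column
#' @return data.frame: gene_id, rho, p, fdr, n (and partial_rho, n_purity)
#' @export
coexpr_table <- function(expr, focal, gene_ids = NULL, purity = NULL) {
  stopifnot(focal %in% rownames(expr))
  if (is.null(gene_ids)) gene_ids <- setdiff(rownames(expr), focal)
  stopifnot(all(gene_ids %in% rownames(expr)))
  n <- ncol(expr)
  rank_rows <- function(m) t(apply(m, 1, rank))
  R <- rank_rows(expr[gene_ids, , drop = FALSE])
  rf <- rank(expr[focal, ])
  sds <- apply(R, 1, stats::sd)
  rho <- rep(NA_real_, length(gene_ids))
  nz <- sds > 0 & stats::sd(rf) > 0
  if (any(nz)) {
    rho[nz] <- drop(stats::cor(rf, t(R[nz, , drop = FALSE])))
  }
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  out <- data.frame(gene_id = gene_ids, rho = rho, p = p,
                    fdr = bh_adjust(p), n = n, stringsAsFactors = FALSE)
  if (!is.null(purity)) {
    stopifnot(length(purity) == n)
    keep <- !is.na(purity)
    np <- sum(keep)
    if (np < 3) stop("fewer than 3 samples with purity values")
    Rp <- rank_rows(expr[gene_ids, keep, drop = FALSE])
    rfp <- rank(expr[focal, keep])
    rz <- rank(purity[keep])
    E <- residualize_ranks(Rp, rz)
    ef <- drop(residualize_ranks(matrix(rfp, nrow = 1), rz))
    prho <- rep(NA_real_, length(gene_ids))
    nzp <- apply(E, 1, stats::sd) > 0 & stats::sd(ef) > 0
    if (any(nzp)) {
      prho[nzp] <- drop(stats::cor(ef, t(E[nzp, , drop = FALSE])))
    }
    out$partial_rho <- prho
    # significance of the partial correlation: t with n - 3 df
    tp <- prho * sqrt((np - 3) / pmax(1 - prho^2, .Machine$double.eps))
    out$partial_p <- 2 * stats::pt(-abs(tp), np - 3)
    out$n_purity <- np
  }
  out
}

#' Random-gene-set permutation null for co-expression metrics
#'
#' Computes the observed co-expression metrics of a target gene set with
#' the focal gene (number of significant positive correlations at
#' unadjusted p < alpha, median rho, mean rho; the BH-significant count is
#' reported alongside) and compares them to `n_sets` equal-size random
#' gene sets drawn without replacement from the expressed background.
#' Per-gene correlations are computed once; draws subset them, so large
#' `n_sets` is cheap. Empirical p-values use the add-one convention.
#'
#' @param expr genes x samples matrix (log2(TPM + 1)), tumor samples
#' @param focal focal gene row id
#' @param target_genes character vector of target gene ids
#' @param seed integer seed
#' @param n_sets random sets (default 10,000)
#' @param background optional background gene ids; default: genes with a
#'   nonzero value in >= `expressed_frac` of samples, focal excluded
#' @param alpha significance level for the count metric (default 0.05)
#' @param purity optional per-sample purity; switches all correlations to
#'   the purity-corrected partial Spearman (samples without purity dropped)
#' @param expressed_frac background expression threshold (default 0.2)
#' @return a `geneset_null` object: observed metrics, null draws, empirical
#'   p per metric, n_sets, seed
#' @export
random_geneset_null <- function(expr, focal, target_genes, seed,
                                n_sets = 10000, background = NULL,
                                alpha = 0.05, purity = NULL,
                                expressed_frac = 0.2) {
  stopifnot(all(target_genes %in% rownames(expr)))
  if (is.null(background)) {
    frac_nonzero <- rowMeans(expr > 0)
    background <- rownames(expr)[frac_nonzero >= expressed_frac]
    background <- union(background, target_genes)
  }
  background <- setdiff(background, focal)
  k <- length(target_genes)
  if (length(background) < k) {
    stop(sprintf("background (%d genes) smaller than the target set (%d)",
                 length(background), k))
  }
  tab <- coexpr_table(expr, focal, gene_ids = background, purity = purity)
  rho <- if (is.null(purity)) tab$rho else tab$partial_rho
  p <- if (is.null(purity)) tab$p else tab$partial_p
  names(rho) <- names(p) <- tab$gene_id
  fdr <- stats::setNames(tab$fdr, tab$gene_id)
  metrics <- function(ids) {
    r <- rho[ids]; pv <- p[ids]
    c(n_sig_pos = sum(r > 0 & pv < alpha, na.rm = TRUE),
      median_rho = stats::median(r, na.rm = TRUE),
      mean_rho = mean(r, na.rm = TRUE))
  }
  observed <- metrics(target_genes)
  observed_fdr_sig <- sum(rho[target_genes] > 0 &
                            bh_adjust(p[target_genes]) < alpha, na.rm = TRUE)
  null <- with_seed(seed, {
    t(vapply(seq_len(n_sets),
             function(i) metrics(sample(background, k)),
             numeric(3)))
  })
  p_emp <- vapply(seq_along(observed), function(j) {
    empirical_p(observed[j], null[, j])
  }, numeric(1))
  names(p_emp) <- names(observed)
  structure(list(observed = observed, observed_fdr_sig = observed_fdr_sig,
                 null = null, p = p_emp, set_size = k, n_sets = n_sets,
                 seed = seed, purity_corrected = !is.null(purity),
                 alpha = alpha),
            class = "geneset_null")
}

#' @export
print.geneset_null <- function(x, ...) {
  cat(sprintf(
    "Random gene-set null (%d sets of %d genes%s):\n", x$n_sets, x$set_size,
    if (x$purity_corrected) ", purity-corrected" else ""))
  for (m in names(x$observed)) {
    cat(sprintf("  %s: observed %.4g vs null %.4g +/- %.4g, p = %.4g\n",
                m, x$observed[m], mean(x$null[, m]), stats::sd(x$null[, m]),
                x$p[m]))
  }
  invisible(x)
}
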