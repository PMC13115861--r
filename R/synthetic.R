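#' Simulation configuration
#'
#' Desk-sized study emulation with planted ground truth: a 3 x 6 Mb toy
#' genome partitioned into 300 kb slots; super-enhancers, contact peaks,
#' correlation peaks and genes are laid out in disjoint slot bands so every
#' planted signal is recoverable by construction and every noise element is
#' guaranteed not to survive the pipeline's filters. See the methods
#' vignette for the layout.
#'
#' @param seed integer seed (mandatory; every output is a deterministic
#'   function of the config and this seed)
#' @param n_chroms,chrom_len genome specification
#' @param n_replicates contact replicates
#' @param n_bg_contacts background true contact peaks (outside SEs)
#' @param contact_width_range true peak width range (bp)
#' @param contact_jitter max per-fraction placement jitter (bp)
#' @param noise_lambda Poisson mean of fraction-private noise peaks per
#'   replicate x fraction
#' @param pad odd/even reconciliation pad (bp)
#' @param n_cancer_specific,n_normal_specific,n_shared planted SE mix
#' @param n_cancer_samples,n_normal_samples per-condition SE samples
#' @param cancer_min_support,normal_min_support consensus support rules
#' @param se_width_range planted SE width range (bp)
#' @param se_jitter per-sample SE boundary jitter (bp)
#' @param intra_gap within-sample SE stitching distance (bp)
#' @param n_psi planted lncRNA-reactive (psi) SEs among the cancer-specific
#' @param n_omega_contacted omega SEs given exactly one contact peak
#' @param n_extra_lncrnas additional lncRNAs for the ranking comparison
#' @param n_focal_bg_confirmed,n_focal_bg_unconfirmed focal correlation
#'   peaks outside SEs, with/without a coincident contact
#' @param window,tpm_min target-assignment defaults planted against
#' @param n_tumor,n_normal_cohort tumor cohort sizes
#' @param purity_frac fraction of tumor samples with a purity estimate
#' @param beta_coupling focal-activity coupling of planted co-expressed
#'   genes (log2 units per activity sd)
#' @param beta_anti coupling of planted anti-correlated decoy genes
#' @param gamma_purity purity effect on confounded genes (log2 units)
#' @param cohort_shift_up,cohort_shift_down planted tumor-vs-normal log2
#'   shifts
#' @param cell_shift_up,cell_shift_down planted cell-line log2 shifts
#' @param cell_noise_sd,cohort_noise_sd replicate/sample noise (log2 units)
#' @return a `sim_config` list
#' @export
simulation_config <- function(seed,
                              n_chroms = 3, chrom_len = 6e6,
                              n_replicates = 3,
                              n_bg_contacts = 90,
                              contact_width_range = c(300, 800),
                              contact_jitter = 50,
                              noise_lambda = 12,
                              pad = 250,
                              n_cancer_specific = 18,
                              n_normal_specific = 12,
                              n_shared = 6,
                              n_cancer_samples = 3,
                              n_normal_samples = 6,
                              cancer_min_support = 3,
                              normal_min_support = 5,
                              se_width_range = c(20000, 40000),
                              se_jitter = 300,
                              intra_gap = 12500,
                              n_psi = 7,
                              n_omega_contacted = 6,
                              n_extra_lncrnas = 49,
                              n_focal_bg_confirmed = 20,
                              n_focal_bg_unconfirmed = 40,
                              window = 100000,
                              tpm_min = 1,
                              n_tumor = 120,
                              n_normal_cohort = 20,
                              purity_frac = 0.9,
                              beta_coupling = 0.6,
                              beta_anti = -0.35,
                              gamma_purity = 0.8,
                              cohort_shift_up = 1.5,
                              cohort_shift_down = -1,
                              cell_shift_up = 3.5,
                              cell_shift_down = -3,
                              cell_noise_sd = 0.25,
                              cohort_noise_sd = 0.5) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  cfg$focal_id <- "lncF"
  cfg$slot_size <- 300000
  stopifnot(n_psi <= n_cancer_specific,
            n_omega_contacted <= n_cancer_specific - n_psi,
            cancer_min_support <= n_cancer_samples,
            normal_min_support <= n_normal_samples)
  structure(cfg, class = "sim_config")
}

# Slot layout: deterministic interleaving of SE roles over 300 kb slots.
# Within a used slot the SE body sits at [130 kb, 130 kb + width); the
# 100 kb target-window band [30 kb, 270 kb) never leaves the slot. Free
# slots host background contacts and genes (band A, 20-200 kb) and
# fraction-private noise / blacklist regions (band B, 210-290 kb).
sim_layout <- function(cfg) {
  slots_per_chrom <- floor(cfg$chrom_len / cfg$slot_size)
  n_slots <- cfg$n_chroms * slots_per_chrom
  roles <- rep("free", n_slots)
  c_slots <- seq(1, by = 3, length.out = cfg$n_cancer_specific)
  s_slots <- seq(2, by = 9, length.out = cfg$n_shared)
  pool2 <- setdiff(seq(2, n_slots, by = 3), s_slots)
  nrm_slots <- pool2[seq_len(cfg$n_normal_specific)]
  pool0 <- seq(3, n_slots, by = 3)
  cd_slots <- pool0[c(2, 7, 12)]
  nd_slots <- pool0[c(17, length(pool0))]
  if (anyNA(c(c_slots, s_slots, nrm_slots, cd_slots, nd_slots)) ||
      max(c(c_slots, s_slots, nrm_slots, cd_slots, nd_slots)) > n_slots) {
    stop("genome too small for the requested SE mix")
  }
  roles[c_slots] <- "cancer"
  roles[s_slots] <- "shared"
  roles[nrm_slots] <- "normal"
  roles[cd_slots] <- "cancer_decoy"
  roles[nd_slots] <- "normal_decoy"
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  slot_chrom <- chroms[(seq_len(n_slots) - 1) %/% slots_per_chrom + 1]
  slot_start <- ((seq_len(n_slots) - 1) %% slots_per_chrom) * cfg$slot_size
  list(roles = roles, chrom = slot_chrom, start = slot_start,
       chroms = chroms, n_slots = n_slots,
       sizes = stats::setNames(rep(cfg$chrom_len, cfg$n_chroms), chroms))
}

#' Simulate the full input bundle with ground truth
#'
#' Generates every input the pipeline consumes - replicate odd/even/input
#' contact fractions, a blacklist, per-sample SE annotations, the
#' multi-lncRNA correlation peak table, gene annotation, cell-line TPM
#' replicate tables and the derived DE table, and a tumor cohort expression
#' matrix with purity metadata - together with the planted truth each stage
#' should recover.
#'
#' @param cfg a [simulation_config()]
#' @return list with `inputs` (everything [run_pipeline()] needs), `truth`
#'   (planted expectations) and `config`
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_study_impl(cfg))
}

simulate_study_impl <- function(cfg) {
  lay <- sim_layout(cfg)
  sizes <- lay$sizes
  jit <- function(n) sample(seq(-cfg$contact_jitter, cfg$contact_jitter), n,
                            replace = TRUE)

  ## ---- planted super-enhancers -------------------------------------------
  se_slots <- which(lay$roles %in% c("cancer", "shared", "cancer_decoy",
                                     "normal", "normal_decoy"))
  se_plan <- data.frame(slot = se_slots, role = lay$roles[se_slots],
                        stringsAsFactors = FALSE)
  se_plan$width <- round(stats::runif(nrow(se_plan), cfg$se_width_range[1],
                                      cfg$se_width_range[2]))
  se_plan$chrom <- lay$chrom[se_plan$slot]
  se_plan$start <- lay$start[se_plan$slot] + 130000
  se_plan$end <- se_plan$start + se_plan$width

  cancer_idx <- which(se_plan$role == "cancer")
  psi_idx <- cancer_idx[seq_len(cfg$n_psi)]
  omega_idx <- setdiff(cancer_idx, psi_idx)
  n_om <- length(omega_idx)
  omega_contacted_idx <- omega_idx[seq_len(cfg$n_omega_contacted)]
  # decoy correlation peaks (no coincident contact): 3 contacted + up to 2
  # non-contacted omega SEs, probing that contact confirmation, not SE
  # overlap, drives the psi label
  decoy_corr_idx <- unique(c(
    omega_contacted_idx[seq_len(min(3, cfg$n_omega_contacted))],
    omega_idx[omega_idx > max(omega_contacted_idx)][
      seq_len(min(2, n_om - cfg$n_omega_contacted))]))
  # promoter-mode omega SEs: a confirmed peak at the target gene TSS only
  tssmode_pool <- setdiff(omega_idx, c(omega_contacted_idx, decoy_corr_idx))
  tssmode_idx <- tssmode_pool[seq_len(min(2, length(tssmode_pool)))]
  # boundary-fidelity SEs: planted without per-sample jitter so the exact
  # 100 kb / TPM-threshold boundary genes stay exact
  boundary_idx <- c(psi_idx[min(2, length(psi_idx))], omega_idx[4])
  frag_idx <- cancer_idx[min(5, length(cancer_idx))]

  # expected consensus ids (genomic order = slot order)
  in_cancer_cons <- se_plan$role %in% c("cancer", "shared")
  se_plan$cancer_se_id <- NA_character_
  se_plan$cancer_se_id[in_cancer_cons] <-
    sprintf("se_%d", seq_len(sum(in_cancer_cons)))
  in_normal_cons <- se_plan$role %in% c("normal", "shared")
  se_plan$normal_se_id <- NA_character_
  se_plan$normal_se_id[in_normal_cons] <-
    sprintf("nse_%d", seq_len(sum(in_normal_cons)))

  se_jit <- function(idx) {
    j <- sample(seq(-cfg$se_jitter, cfg$se_jitter), length(idx), replace = TRUE)
    j[idx %in% boundary_idx] <- 0L
    j
  }
  sample_rows <- function(idx, split_frag = FALSE) {
    df <- data.frame(chrom = se_plan$chrom[idx],
                     start = se_plan$start[idx] + se_jit(idx),
                     end = se_plan$end[idx] + se_jit(idx),
                     stringsAsFactors = FALSE)
    if (split_frag && frag_idx %in% idx) {
      k <- which(idx == frag_idx)
      w <- df$end[k] - df$start[k]
      cut1 <- df$start[k] + round(0.3 * w)
      piece2 <- data.frame(chrom = df$chrom[k], start = cut1 + 10000,
                           end = df$end[k], stringsAsFactors = FALSE)
      stopifnot(piece2$start < piece2$end)  # gap 10 kb < intra_gap: re-merges
      df$end[k] <- cut1
      df <- rbind(df, piece2)
    }
    df
  }
  cancer_samples <- lapply(seq_len(cfg$n_cancer_samples), function(s) {
    idx <- which(se_plan$role %in% c("cancer", "shared") |
                   (se_plan$role == "cancer_decoy" & s <= 2))
    se_sample(sprintf("cancer_%d", s), "cancer",
              sample_rows(idx, split_frag = (s == 1)))
  })
  normal_samples <- lapply(seq_len(cfg$n_normal_samples), function(s) {
    ni <- which(se_plan$role == "normal")
    j <- seq_along(ni)
    # alternate support: odd-j SEs absent from exactly one sample (5 of 6),
    # even-j SEs in all samples
    absent_in <- (j %% cfg$n_normal_samples) + 1
    keep_n <- ni[!(j %% 2 == 1 & absent_in == s)]
    idx <- sort(c(keep_n,
                  which(se_plan$role == "shared" &
                          s <= cfg$normal_min_support),
                  which(se_plan$role == "normal_decoy" &
                          s <= cfg$normal_min_support - 1)))
    se_sample(sprintf("colon_%d", s), "normal", sample_rows(idx))
  })

  ## ---- true contact peaks ------------------------------------------------
  cw <- function(n) round(stats::runif(n, cfg$contact_width_range[1],
                                       cfg$contact_width_range[2]))
  body_pos <- function(idx, frac) round(se_plan$start[idx] +
                                          frac * se_plan$width[idx])
  contacts <- list()
  psi_contact_counts <- ifelse(seq_along(psi_idx) %% 2 == 1, 3L, 2L)
  for (k in seq_along(psi_idx)) {
    i <- psi_idx[k]
    fr <- c(0.2, 0.5, 0.8)[seq_len(psi_contact_counts[k])]
    st <- body_pos(rep(i, length(fr)), fr)
    contacts[[length(contacts) + 1]] <-
      data.frame(chrom = se_plan$chrom[i], start = st,
                 end = st + cw(length(fr)), where = "psi",
                 stringsAsFactors = FALSE)
  }
  for (i in omega_contacted_idx) {
    st <- body_pos(i, 0.2)
    contacts[[length(contacts) + 1]] <-
      data.frame(chrom = se_plan$chrom[i], start = st, end = st + cw(1),
                 where = "omega", stringsAsFactors = FALSE)
  }
  # promoter-mode contacts sit at the downstream target gene's TSS
  # (strand-aware), outside every SE body
  tss_k <- match(tssmode_idx, cancer_idx)
  tss_gene_start <- se_plan$end[tssmode_idx] + 30000  # gene B start (below)
  tss_pos <- tss_gene_start + ifelse(tss_k %% 2 == 0, 11999, 0)
  for (t in seq_along(tssmode_idx)) {
    st <- tss_pos[t] - 150
    contacts[[length(contacts) + 1]] <-
      data.frame(chrom = se_plan$chrom[tssmode_idx[t]], start = st,
                 end = st + cw(1), where = "tss", stringsAsFactors = FALSE)
  }
  free_slots <- which(lay$roles == "free")
  bg_per_slot <- ceiling(cfg$n_bg_contacts / length(free_slots))
  bg <- do.call(rbind, lapply(free_slots, function(sl) {
    offs <- 20000 + (seq_len(bg_per_slot) - 1) * 12000
    data.frame(chrom = lay$chrom[sl], start = lay$start[sl] + offs,
               end = lay$start[sl] + offs + cw(bg_per_slot),
               where = "background", stringsAsFactors = FALSE)
  }))
  bg <- bg[seq_len(cfg$n_bg_contacts), , drop = FALSE]
  true_contacts <- iv_sort(rbind(do.call(rbind, contacts), bg))
  n_true <- nrow(true_contacts)
  # every 5th background peak is supported by only 2 of the 3 replicates
  support <- rep(list(seq_len(cfg$n_replicates)), n_true)
  bg_rows <- which(true_contacts$where == "background")
  for (r in bg_rows[seq_along(bg_rows) %% 5 == 0]) {
    support[[r]] <- sort(sample(cfg$n_replicates, 2))
  }

  ## ---- blacklist + artifact peaks ----------------------------------------
  bl_slots <- free_slots[seq_len(min(5, length(free_slots)))]
  blacklist <- data.frame(chrom = lay$chrom[bl_slots],
                          start = lay$start[bl_slots] + 210000,
                          end = lay$start[bl_slots] + 212000,
                          stringsAsFactors = FALSE)
  artifacts <- data.frame(chrom = blacklist$chrom[1:3],
                          start = blacklist$start[1:3] + 500,
                          end = blacklist$start[1:3] + 900,
                          stringsAsFactors = FALSE)

  ## ---- fraction files: true peaks + private noise + artifacts ------------
  noise_pool <- do.call(rbind, lapply(free_slots, function(sl) {
    offs <- 220000 + (0:34) * 2000
    data.frame(chrom = lay$chrom[sl], start = lay$start[sl] + offs,
               stringsAsFactors = FALSE)
  }))
  noise_pool <- noise_pool[sample.int(nrow(noise_pool)), , drop = FALSE]
  noise_cursor <- 0L
  fractions <- list()
  for (r in seq_len(cfg$n_replicates)) {
    rep_id <- sprintf("rep%d", r)
    frac_sets <- list()
    for (f in c("odd", "even")) {
      rows <- which(vapply(support, function(s) r %in% s, logical(1)))
      st <- pmax(0, true_contacts$start[rows] + jit(length(rows)))
      pk <- data.frame(chrom = true_contacts$chrom[rows], start = st,
                       end = st + (true_contacts$end[rows] -
                                     true_contacts$start[rows]),
                       stringsAsFactors = FALSE)
      n_noise <- stats::rpois(1, cfg$noise_lambda)
      if (n_noise > 0) {
        take <- noise_pool[noise_cursor + seq_len(n_noise), , drop = FALSE]
        noise_cursor <- noise_cursor + n_noise
        pk <- rbind(pk, data.frame(chrom = take$chrom, start = take$start,
                                   end = take$start + 400,
                                   stringsAsFactors = FALSE))
      }
      pk <- rbind(pk, artifacts)
      frac_sets[[f]] <- fraction_peaks(rep_id, f, pk)
    }
    inp <- noise_pool[noise_cursor + seq_len(10), , drop = FALSE]
    noise_cursor <- noise_cursor + 10L
    frac_sets$input <- fraction_peaks(
      rep_id, "input",
      data.frame(chrom = inp$chrom, start = inp$start, end = inp$start + 1000,
                 stringsAsFactors = FALSE))
    fractions[[rep_id]] <- frac_sets
  }

  ## ---- correlation peaks -------------------------------------------------
  corr_width <- 300
  mark_mix <- data.frame(
    mark = c("H3K4me1", "H3K4me3", "H3K4me3", "H3K4me1", "H3K27ac",
             "H3K27me3", "H3K36me3", "H3K9me3", "H4K20me1"),
    sign = c("+", "-", "+", "-", "+", "+", "+", "+", "+"),
    w = c(0.45, 0.15, 0.12, 0.08, 0.06, 0.05, 0.05, 0.02, 0.02),
    stringsAsFactors = FALSE)
  draw_marks <- function(n) {
    k <- sample.int(nrow(mark_mix), n, replace = TRUE, prob = mark_mix$w)
    mark_mix[k, c("mark", "sign")]
  }
  corr <- list()
  add_corr <- function(chrom, start, lnc) {
    n <- length(start)
    marks <- draw_marks(n)
    data.frame(chrom = chrom, start = start, end = start + corr_width,
               lncrna_id = lnc, mark = marks$mark, sign = marks$sign,
               stringsAsFactors = FALSE)
  }
  for (k in seq_along(psi_idx)) {  # focal peaks on psi body contacts
    i <- psi_idx[k]
    fr <- if (k %% 2 == 1) c(0.2, 0.5) else 0.2
    st <- body_pos(rep(i, length(fr)), fr) + 50
    corr[[length(corr) + 1]] <- add_corr(se_plan$chrom[i], st, cfg$focal_id)
  }
  n_psi_peaks <- sum(vapply(corr, nrow, integer(1)))
  for (i in decoy_corr_idx) {      # decoys: inside omega body, off-contact
    corr[[length(corr) + 1]] <-
      add_corr(se_plan$chrom[i], body_pos(i, 0.35), cfg$focal_id)
  }
  for (t in seq_along(tssmode_idx)) {  # promoter-mode: on the TSS contact
    corr[[length(corr) + 1]] <-
      add_corr(se_plan$chrom[tssmode_idx[t]], tss_pos[t] - 100, cfg$focal_id)
  }
  conf_rows <- bg_rows[seq_len(cfg$n_focal_bg_confirmed)]
  corr[[length(corr) + 1]] <- add_corr(true_contacts$chrom[conf_rows],
                                       true_contacts$start[conf_rows] + 20,
                                       cfg$focal_id)
  unconf <- do.call(rbind, lapply(free_slots, function(sl) {
    offs <- 150000 + (0:3) * 4000
    data.frame(chrom = lay$chrom[sl], start = lay$start[sl] + offs,
               stringsAsFactors = FALSE)
  }))
  unconf <- unconf[seq_len(cfg$n_focal_bg_unconfirmed), , drop = FALSE]
  corr[[length(corr) + 1]] <- add_corr(unconf$chrom, unconf$start, cfg$focal_id)
  extra_counts <- integer(0)
  if (cfg$n_extra_lncrnas > 0) {
    extra_counts <- sample(0:max(0, cfg$n_cancer_specific - 3),
                           cfg$n_extra_lncrnas, replace = TRUE)
    for (j in seq_len(cfg$n_extra_lncrnas)) {
      cj <- extra_counts[j]
      lnc <- sprintf("lnc_extra%02d", j)
      if (cj == 0) {  # present in the table, zero SE overlap
        sl <- free_slots[1 + (j %% length(free_slots))]
        corr[[length(corr) + 1]] <-
          add_corr(lay$chrom[sl], lay$start[sl] + 190000 + (j %% 8) * 450, lnc)
      } else {
        tgt <- cancer_idx[seq_len(cj)]
        corr[[length(corr) + 1]] <-
          add_corr(se_plan$chrom[tgt], body_pos(tgt, 0.62) + (j %% 5) * 450,
                   lnc)
      }
    }
  }
  corr_peaks <- iv_sort(do.call(rbind, corr))

  ## ---- genes -------------------------------------------------------------
  gene_rows <- list()
  gid <- 0
  add_gene <- function(chrom, start, end, strand, biotype, role, se = NA) {
    gid <<- gid + 1
    data.frame(gene_id = sprintf("G%04d", gid),
               symbol = sprintf("GENE%04d", gid),
               chrom = chrom, start = start, end = end, strand = strand,
               biotype = biotype, role = role, se_idx = se,
               stringsAsFactors = FALSE)
  }
  # target roles: triple (planted triple-validated), t1 (cell-line down),
  # t2 (cell-line unchanged), t3 (up in both but anti-correlated with the
  # focal lncRNA), null/down for omega targets
  patternA <- rep_len(c("triple", "t1", "triple", "t2", "triple", "t3",
                        "triple"), length(psi_idx))
  patternB <- rep_len(c("triple", "t3", "triple", "t2", "t1", "triple",
                        "triple"), length(psi_idx))
  roleA <- c(patternA, rep_len(c("null", "down"), n_om))
  roleB <- c(patternB, rep_len(c("down", "null"), n_om))
  for (k in seq_along(cancer_idx)) {
    i <- cancer_idx[k]
    strand <- if (k %% 2 == 0) "-" else "+"
    gene_rows[[length(gene_rows) + 1]] <-    # gene A: overlaps the SE body
      add_gene(se_plan$chrom[i], se_plan$start[i] + 5000,
               se_plan$start[i] + 15000, strand, "protein_coding",
               roleA[k], i)
    gene_rows[[length(gene_rows) + 1]] <-    # gene B: 30 kb downstream
      add_gene(se_plan$chrom[i], se_plan$end[i] + 30000,
               se_plan$end[i] + 42000, strand, "protein_coding",
               roleB[k], i)
  }
  # boundary cases at the two jitter-free SEs: start exactly `window` bp
  # from the SE end (kept), window + 1 (excluded), and an overlapping gene
  # with mean TPM exactly tpm_min (excluded by the strict > rule)
  bnd_roles <- c("t2", "null")
  for (b in seq_along(boundary_idx)) {
    i <- boundary_idx[b]
    gene_rows[[length(gene_rows) + 1]] <-
      add_gene(se_plan$chrom[i], se_plan$end[i] + cfg$window,
               se_plan$end[i] + cfg$window + 8000, "+", "protein_coding",
               bnd_roles[b], i)
    gene_rows[[length(gene_rows) + 1]] <-
      add_gene(se_plan$chrom[i], se_plan$end[i] + cfg$window + 1,
               se_plan$end[i] + cfg$window + 9000, "+", "protein_coding",
               "excluded_window", i)
    gene_rows[[length(gene_rows) + 1]] <-
      add_gene(se_plan$chrom[i], se_plan$start[i] + 2000,
               se_plan$start[i] + 9000, "-", "protein_coding",
               "excluded_tpm", i)
  }
  bg_gene_roles <- rep_len(c("null", "confounded", "down", "null", "up_bg"),
                           3 * length(free_slots))
  bi <- 0
  for (sl in free_slots) {
    for (g in 1:3) {
      bi <- bi + 1
      st <- lay$start[sl] + 30000 + (g - 1) * 45000
      gene_rows[[length(gene_rows) + 1]] <-
        add_gene(lay$chrom[sl], st, st + 12000,
                 if (bi %% 2 == 0) "-" else "+", "protein_coding",
                 bg_gene_roles[bi])
    }
  }
  foc_sl <- free_slots[1]
  gene_rows[[length(gene_rows) + 1]] <-
    add_gene(lay$chrom[foc_sl], lay$start[foc_sl] + 190000,
             lay$start[foc_sl] + 195000, "+", "lncRNA", "focal")
  focal_gene_id <- gene_rows[[length(gene_rows)]]$gene_id
  for (j in 1:3) {
    sl <- free_slots[1 + j]
    gene_rows[[length(gene_rows) + 1]] <-
      add_gene(lay$chrom[sl], lay$start[sl] + 195000,
               lay$start[sl] + 199000, "+", "lncRNA", "null_lnc")
  }
  genes <- do.call(rbind, gene_rows)

  ## ---- cell-line expression (TPM replicates) -----------------------------
  n_genes <- nrow(genes)
  is_target <- !is.na(genes$se_idx) &
    !(genes$role %in% c("excluded_tpm", "excluded_window"))
  base <- stats::runif(n_genes, 2, 6)
  base[is_target | genes$role %in% c("excluded_window", "focal")] <-
    stats::runif(sum(is_target | genes$role %in% c("excluded_window", "focal")),
                 4, 6)  # targets stay expressed even under a planted down-shift
  cell_shift <- rep(0, n_genes)
  cell_shift[genes$role %in% c("triple", "t3", "up_bg", "focal")] <-
    cfg$cell_shift_up
  cell_shift[genes$role %in% c("t1", "down")] <- cfg$cell_shift_down
  n_cc <- 3; n_cn <- 4
  clamp0 <- function(m) { m[m < 0] <- 0; m }
  l_cancer <- clamp0(base + cell_shift / 2 +
                       matrix(stats::rnorm(n_genes * n_cc, 0, cfg$cell_noise_sd),
                              n_genes, n_cc))
  l_normal <- clamp0(base - cell_shift / 2 +
                       matrix(stats::rnorm(n_genes * n_cn, 0, cfg$cell_noise_sd),
                              n_genes, n_cn))
  tpm1 <- genes$role == "excluded_tpm"
  l_cancer[tpm1, ] <- log2(cfg$tpm_min + 1)  # mean TPM exactly at threshold
  l_normal[tpm1, ] <- log2(cfg$tpm_min + 1)
  rownames(l_cancer) <- rownames(l_normal) <- genes$gene_id
  colnames(l_cancer) <- sprintf("cell_rep%d", seq_len(n_cc))
  colnames(l_normal) <- sprintf("organoid_rep%d", seq_len(n_cn))
  tpm_cancer_mat <- 2^l_cancer - 1
  tpm_normal_mat <- 2^l_normal - 1
  genes$tpm_cancer <- rowMeans(tpm_cancer_mat)
  genes$tpm_normal <- rowMeans(tpm_normal_mat)
  de_cell <- welch_de(cbind(l_cancer, l_normal),
                      c(rep("tumor", n_cc), rep("normal", n_cn)))

  ## ---- tumor cohort ------------------------------------------------------
  nT <- cfg$n_tumor; nN <- cfg$n_normal_cohort
  activity <- stats::rnorm(nT)
  purity <- stats::runif(nT, 0.25, 0.95)
  beta <- rep(0, n_genes)
  beta[genes$role %in% c("triple", "focal")] <- cfg$beta_coupling
  beta[genes$role == "t3"] <- cfg$beta_anti
  gamma <- rep(0, n_genes)
  gamma[genes$role %in% c("confounded", "focal", "triple")] <- cfg$gamma_purity
  cshift <- rep(0, n_genes)
  cshift[genes$role %in% c("triple", "t3", "up_bg", "focal")] <-
    cfg$cohort_shift_up
  cshift[genes$role %in% c("t1", "down")] <- cfg$cohort_shift_down
  cohort_base <- stats::runif(n_genes, 2, 6)
  tumor_part <- outer(cshift, rep(1, nT)) +
    beta %o% activity + gamma %o% purity
  expr <- cbind(cohort_base + tumor_part, matrix(cohort_base, n_genes, nN))
  expr <- clamp0(expr + matrix(stats::rnorm(n_genes * (nT + nN), 0,
                                            cfg$cohort_noise_sd),
                               n_genes, nT + nN))
  rn <- genes$gene_id
  rn[genes$role == "focal"] <- cfg$focal_id  # co-expression anchors on this id
  rownames(expr) <- rn
  purity_out <- c(purity, rep(NA_real_, nN))
  n_missing <- round((1 - cfg$purity_frac) * nT)
  if (n_missing > 0) purity_out[sample(nT, n_missing)] <- NA
  meta <- data.frame(sample = sprintf("S%03d", seq_len(nT + nN)),
                     class = c(rep("tumor", nT), rep("normal", nN)),
                     purity = purity_out, stringsAsFactors = FALSE)
  colnames(expr) <- meta$sample

  ## ---- ground truth ------------------------------------------------------
  assoc <- genes[is_target, c("gene_id", "role", "se_idx")]
  truth_assoc <- data.frame(
    se_id = se_plan$cancer_se_id[assoc$se_idx],
    gene_id = assoc$gene_id, role = assoc$role, stringsAsFactors = FALSE)
  truth_assoc <- truth_assoc[order(truth_assoc$se_id, truth_assoc$gene_id,
                                   method = "radix"), ]
  rownames(truth_assoc) <- NULL
  tss_truth <- data.frame(
    se_id = se_plan$cancer_se_id[tssmode_idx],
    gene_id = genes$gene_id[match(
      paste(se_plan$chrom[tssmode_idx], tss_gene_start),
      paste(genes$chrom, genes$start))],
    stringsAsFactors = FALSE)
  lnc_counts <- c(
    stats::setNames(length(psi_idx) + length(decoy_corr_idx), cfg$focal_id),
    stats::setNames(extra_counts,
                    sprintf("lnc_extra%02d", seq_along(extra_counts))))
  truth <- list(
    n_contact_peaks = n_true,
    contact_intervals = true_contacts[, c("chrom", "start", "end")],
    n_artifact_peaks = nrow(artifacts),
    se_plan = se_plan,
    class_counts = c(cancer_specific = cfg$n_cancer_specific,
                     normal_specific = cfg$n_normal_specific,
                     shared = cfg$n_shared),
    psi_se_ids = se_plan$cancer_se_id[psi_idx],
    omega_contacted_ids = se_plan$cancer_se_id[omega_contacted_idx],
    decoy_se_ids = se_plan$cancer_se_id[decoy_corr_idx],
    tss_mode = tss_truth,
    n_confirmed = n_psi_peaks + length(tssmode_idx) +
      cfg$n_focal_bg_confirmed,
    psi_contact_counts = psi_contact_counts,
    associations = truth_assoc,
    triple_genes = sort(genes$gene_id[genes$role == "triple"]),
    focal_gene_id = focal_gene_id,
    lnc_se_counts = lnc_counts,
    beta = stats::setNames(beta, rownames(expr)),
    gamma = stats::setNames(gamma, rownames(expr)))

  inputs <- list(
    sizes = sizes,
    fractions = fractions,
    blacklist = blacklist,
    se_samples = c(cancer_samples, normal_samples),
    corr_peaks = corr_peaks,
    genes = genes[, setdiff(names(genes), c("role", "se_idx"))],
    tpm_cell = list(cancer = tpm_cancer_mat, normal = tpm_normal_mat),
    de_cell = de_cell,
    cohort = list(expr = expr, meta = meta),
    focal_id = cfg$focal_id)
  list(inputs = inputs, truth = truth, config = cfg)
}

#' Simulate a purity-confounded expression pair
#'
#' Generates `(x, y, z)` where `z` is a purity-like confounder acting on
#' both `x` and `y` with coefficient `gamma`, and the direct (purity-free)
#' association between `x` and `y` is a bivariate Gaussian component whose
#' Spearman correlation equals `planted_rho`. With `planted_rho = 0` any
#' ordinary correlation between x and y is pure confounding.
#'
#' @param n sample size
#' @param planted_rho target direct Spearman correlation
#' @param gamma confounder coefficient
#' @param seed integer seed
#' @param noise_sd sd of the Gaussian component (default 0.3)
#' @return data.frame with columns x, y, z
#' @export
simulate_confounded_pair <- function(n, planted_rho, gamma, seed,
                                     noise_sd = 0.3) {
  r_pearson <- 2 * sin(pi * planted_rho / 6)  # Spearman -> Pearson, Gaussian
  with_seed(seed, {
    z <- stats::runif(n, 0.25, 0.95)
    e1 <- stats::rnorm(n, 0, noise_sd)
    e2 <- r_pearson * e1 + sqrt(1 - r_pearson^2) * stats::rnorm(n, 0, noise_sd)
    data.frame(x = gamma * z + e1, y = gamma * z + e2, z = z)
  })
}
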