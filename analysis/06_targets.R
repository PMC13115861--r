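#!/usr/bin/env Rscript
# Stage 6: target-gene assignment, lead genes, and cohort DE.
#
# A gene is a target of an SE if it is expressed (mean TPM > 1) and
# overlaps the SE or starts within 100 kb of an SE boundary. The lead
# gene of each SE is the target with the lowest adjusted p in the
# cell-line DE table. Tumor-vs-normal differential expression in the
# cohort uses Welch's t-test on log2(TPM + 1). Promoter-mode omega SEs
# (confirmed marks at a target TSS but not on the SE body) are reported.

suppressMessages(library(lncsemap))

inp <- load_study_inputs("results/sim_bundle")
atlas <- read_tsv_table("results/se_atlas.tsv")
cancer_specific <- atlas[atlas$specificity == "cancer-specific", ]
cls <- read_tsv_table("results/se_classification.tsv")
contacts <- read_tsv_table("results/contact_provenance.tsv")

assocs <- assign_targets(cancer_specific, inp$genes, window = 100000,
                         tpm_min = 1, tpm_col = "tpm_cancer")
lg <- lead_gene(assocs, inp$de_cell)
write_tsv_table(lg$assocs, "results/associations.tsv")
write_tsv_table(lg$leads, "results/lead_genes.tsv")

de_cohort <- welch_de(inp$cohort$expr, inp$cohort$meta$class)
write_tsv_table(de_cohort, "results/de_cohort.tsv")

focal <- inp$corr_peaks[inp$corr_peaks$lncrna_id == inp$focal_id, ]
confirmed <- confirm_peaks(focal, contacts)
tssm <- tss_mode(cls, confirmed, inp$genes, assocs, promoter_pad = 2000)
write_tsv_table(tssm$tss_hits, "results/tss_mode.tsv")

cat(sprintf("associations: %d across %d SEs; %d lead genes (%d significant)\n",
            nrow(assocs), length(unique(assocs$se_id)), nrow(lg$leads),
            sum(lg$leads$significant)))
cat(sprintf("cohort DE: %d genes, %d with padj < 0.05\n",
            nrow(de_cohort), sum(de_cohort$padj < 0.05)))
cat(sprintf("promoter-mode omega SEs: %d; psi SE body/TSS concordance: %d of %d\n",
            length(unique(tssm$tss_hits$se_id)),
            sum(tssm$psi_concordance$concordant),
            nrow(tssm$psi_concordance)))
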