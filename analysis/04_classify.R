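#!/usr/bin/env Rscript
# Stage 4: two-stage triple intersection and psi/omega classification.
#
# Correlation peaks of the focal lncRNA that overlap a consensus contact
# peak are "confirmed"; cancer-specific SEs harbouring at least one
# confirmed peak are labelled psi (lncRNA-reactive), the rest omega. Also
# reports mark profiles, per-SE contact density with the one-sided
# Mann-Whitney psi-vs-contacted-omega comparison, and the multi-lncRNA
# SE-overlap ranking of the focal lncRNA.

suppressMessages(library(lncsemap))

inp <- load_study_inputs("results/sim_bundle")
contacts <- read_tsv_table("results/contact_provenance.tsv")
atlas <- read_tsv_table("results/se_atlas.tsv")
cancer_specific <- atlas[atlas$specificity == "cancer-specific", ]

focal <- inp$corr_peaks[inp$corr_peaks$lncrna_id == inp$focal_id, ]
confirmed <- confirm_peaks(focal, contacts)
cls <- classify_ses(cancer_specific, confirmed)
dens <- contact_density(cls$ses, contacts)
write_tsv_table(cls$ses, "results/se_classification.tsv")
write_tsv_table(cls$profiles, "results/mark_profiles.tsv")
write_tsv_table(dens, "results/contact_density.tsv")

cat(sprintf("confirmed correlation peaks: %d of %d (%.1f%%)\n",
            nrow(confirmed), nrow(focal),
            summarize_percentage(nrow(confirmed), nrow(focal))))
cat(sprintf("psi SEs: %d of %d (%.1f%%); %d mark instances, %d compound profiles\n",
            cls$summary$n_psi, cls$summary$n_se, cls$summary$pct_psi,
            cls$summary$n_mark_instances, cls$summary$n_compound))

x <- dens$n_contacts[cls$ses$psi == "psi"]
y <- dens$n_contacts[cls$ses$psi == "omega" & dens$n_contacts >= 1]
mw <- mann_whitney_one_sided(x, y)
cat(sprintf("contact density psi vs contacted omega: median %g vs %g, one-sided MW p = %.4g\n",
            median(x), median(y), mw$p))

rk <- lncrna_se_ranking(inp$corr_peaks, cancer_specific, inp$focal_id)
write_tsv_table(rk$counts, "results/lncrna_ranking.tsv")
cat(sprintf("focal lncRNA: %d SEs with >= 1 peak; percentile %.0f among %d lncRNAs with overlap\n",
            rk$focal_count, rk$percentile, rk$n_with_overlap))
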