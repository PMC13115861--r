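---
title: "Mapping lncRNA-chromatin contacts onto super-enhancer landscapes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lncRNA-chromatin contacts onto super-enhancer landscapes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncsemap)
```

## The model

`lncsemap` classifies cancer-specific super-enhancers (SEs) by their
relationship to a focal long non-coding RNA using the conjunction of two
independent evidence layers:

* a **physical layer** — reproducible RNA–chromatin contact peaks of the
  focal lncRNA, built from split-probe ("odd"/"even") replicate peak
  fractions; and
* an **epigenetic layer** — genomic loci where a histone modification's
  signal correlates (positively or negatively) with the lncRNA's
  expression across cell types, annotated with mark and correlation sign.

A correlation peak overlapping a contact peak by at least 1 bp is
*confirmed*: the lncRNA is physically present where chromatin state
covaries with it. A cancer-specific SE harbouring at least one confirmed
peak is labelled **psi** (lncRNA-reactive); the remainder are **omega**.
Neither layer alone suffices: the epigenetic layer marks many SEs for
many lncRNAs (which is why the package also ranks the focal lncRNA among
all lncRNAs by SE coverage), and contact enrichment extends to typical
enhancers; the classification rests on the intersection.

Downstream, psi-SEs acquire target genes by proximity, and candidate
targets are screened by three independent expression criteria
(triple validation): up-regulation in the cancer cell line, up-regulation
in a patient tumor cohort, and positive co-expression with the focal
lncRNA across tumors, with tumor purity removed as a confounder.

All intervals are 0-based half-open (BED convention); "overlap" always
means the half-open ranges share at least one base, so touching intervals
do not overlap. Strand is ignored in all interval arithmetic; gene strand
is used only to locate TSSs.

## Stage conventions and tunable parameters

### Contact consensus

Each replicate's odd and even fractions are symmetrically extended by
`pad` (default 250 bp) and intersected; every intersecting odd/even pair
yields one replicate-supported interval, and unpaired peaks are dropped.
The reconstruction formula this step is conventionally written with —
`start = min(start_even, start_odd) + pad`, `end = max(end_even,
end_odd) − pad` applied to the original coordinates — produces inverted
intervals for short overlapping pairs. We therefore implement two modes:
the default **union** mode reads the min/max as applying to the
pad-extended coordinates, so the result is the union of the two original
peaks; a **literal** mode applies the formula verbatim and drops
degenerate records with a warning. Union mode is the default because it
is the only reading that is well defined on all inputs; the tests pin
both behaviors.

Under half-open arithmetic a ±`pad` extension admits gaps up to
`2·pad − 1` (499 bp at the default), one base short of the 2·pad a rough
reading suggests; the boundary test pins 499 in, 500 out.

Replicate-supported intervals are merged (gap 0) within a replicate, and
an interval is retained iff it overlaps intervals from at least
`min_support − 1` other replicates (default `min_support = 2` of 3).
Retained intervals are pooled and merged; each consensus peak records the
number of replicates overlapping it. Peak calling itself (and its input
control) happens upstream; the input fraction is carried as provenance
only. An ENCODE-style blacklist, when provided, removes whole records
from every fraction before reconciliation.

### SE atlas

Per-sample SE calls are first stitched by merging intervals separated by
strictly less than `intra_gap` (default 12,500 bp, the conventional SE
stitching distance; the strict inequality and the 12,499/12,500 boundary
are pinned by a test). Candidates are then formed by merging the union
across samples with `cross_gap` (default 0, i.e. only
touching/overlapping intervals, matching the merge tool's default
behavior; the distance is a parameter for users who prefer re-using the
stitching gap). A candidate
is kept iff at least `min_support` samples contribute an overlapping
interval (defaults: all 3 cancer samples; 5 of 6 normal samples).
Specificity is assigned at `min_overlap_bp` (default 1 bp): an SE
overlapping the other condition's consensus is "shared", else
condition-specific. For summary totals a shared region is the merged
union of its overlapping cancer and normal intervals, counted once;
psi/omega analysis operates on the cancer-specific set only.

### Psi classification

`confirm_peaks()` demands a single-lncRNA table (a guard against passing
the full multi-lncRNA table) and applies report-once intersection:
confirmed peaks keep their coordinates and annotations. Mark profiles
count **distinct (mark, sign) pairs** per SE — so one SE with three
H3K4me1(+) peaks contributes one mark instance — with per-pair peak
multiplicity reported separately; profiles with ≥2 instances are flagged
compound.

The lncRNA ranking counts, for every lncRNA, the SEs harbouring ≥1 of its
correlation peaks (SE-level presence, so duplicated rows cannot inflate
it), and reports the focal percentile among lncRNAs with count ≥ 1 as
`100 · mean(count ≤ focal count)`. Several percentile conventions are
defensible here; we chose "≤ among lncRNAs with ≥1 overlap" as the
default and expose a strict-`<` variant (`tie_rule = "lt"`).

Promoter-mode detection (`tss_mode`) uses a promoter window of
`promoter_pad` = 2,000 bp on each side of the TSS, a conventional
promoter-proximal window. The TSS is
the annotation start for + strand genes and `end − 1` for − strand;
unknown strand falls back to the start with a warning.

### Permutation statistics

`iv_shuffle()` repositions intervals uniformly at random on their own
chromosome such that placed intervals never overlap (they may touch),
via an exact stars-and-bars construction over integer placements — no
rejection sampling, so placement is provably uniform and always succeeds
when the lengths fit. This matches `bedtools shuffle -chrom
-noOverlapping`, which constrains only chromosome assignment and
overlap; accordingly, shuffling does not avoid the blacklist by default,
and an exclusion set is available as an opt-in argument, honored by
bounded-retry rejection.

Empirical p-values use the add-one convention `p = (k + 1)/(n + 1)` with
`k` the number of null draws ≥ the observed value. This is the only
convention consistent with reporting p = 0.001 for an observed statistic
that exceeds the entire range of 1000 null draws; a saturated test
(k = 0) can alternatively be displayed as an upper bound ("< 0.001").
Per-iteration substream seeds are drawn once from the master seed, so
results do not depend on iteration scheduling, and every
`PermutationResult` stores its draws, seed and iteration count for exact
reproducibility.

The one-sided Mann–Whitney comparison (psi vs other contacted SEs,
alternative "psi greater") uses mid-ranks for ties; for pooled sizes ≤ 12
the p-value is computed by exhaustive enumeration of group assignments,
otherwise by the normal approximation with tie and continuity correction
(matching `wilcox.test` conventions). Enumeration and approximation
agree to about 0.01 on average near the switch point, with worst-case
deviations up to about 0.02 — both paths are exposed.

### Targets and expression

The association window is inclusive (`distance ≤ window`, default
`window = 100,000` bp measured from the gene's annotation start — not
its strand-aware TSS — to the nearer SE boundary, 0 for overlap), and
the expression filter is strict (`TPM > tpm_min`, default 1); both
boundaries are pinned by planted test cases at exactly 100,000 bp and
exactly TPM = 1. Lead-gene ties on adjusted p are broken by larger
|log2FC|, then lexicographic gene id — a deterministic rule chosen by
this package. Genes missing from the DE table are treated as padj = 1
with a warning.

The cell-line DE table is consumed as an input (that comparison is fit
with a dedicated count-based DE model upstream of this package); the
cohort comparison is
Welch's t-test on log2(TPM + 1) with Satterthwaite degrees of freedom,
vectorized over genes, with the degenerate zero-variance/equal-means case
yielding t = 0, p = 1. The triple-validation co-expression criterion uses
unadjusted p < 0.05 with rho > 0 — consistent with the phrasing of the
other two layers — while BH FDR values are carried alongside in every
output.

### Co-expression

Spearman rho is the Pearson correlation of mid-ranks. For n < 10 the
two-sided p is computed by exhaustive enumeration over all n!
permutations; for n ≥ 10 by the t approximation with n − 2 df. The
purity-corrected partial correlation rank-transforms all three vectors,
regresses the ranks of each expression vector on the ranks of purity by
ordinary least squares, and returns the Pearson correlation of the
residuals; with constant purity this reduces *exactly* to the ordinary
Spearman correlation. Samples lacking purity are dropped only in
purity-corrected analyses.

The random-gene-set null draws `n_sets` (default 10,000) equal-size sets
without replacement from the expressed background — genes with a nonzero
value in ≥ 20% of tumor samples (an operational definition of
"expressed"; the threshold is a parameter), excluding the focal gene
but not the targets themselves — and recomputes three metrics per draw:
the number of significant positive correlations (rho > 0, unadjusted
p < 0.05; the BH-significant count is reported as a companion), median
rho, and mean rho. Per-gene correlations are computed once and draws
subset them, so the default 10,000 sets cost little.

## What the synthetic generator emulates — and what it does not

`simulate_study()` emits every input the pipeline consumes, in the real
formats (narrowPeak/BED fractions with a manifest, per-sample SE BEDs,
a correlation-peak TSV with mark/sign vocabulary, gene annotation,
TPM replicate tables, a Welch-derived DE table, a cohort matrix with
purity metadata), on a desk-sized genome of 3 chromosomes × 6 Mb
partitioned into 300 kb slots. Each slot hosts at most one planted SE at
a fixed internal offset, so SE target windows never leak into neighboring
slots, and every planted signal is recoverable exactly:

* true contact peaks appear in both fractions of at least two replicates
  with ≤ 50 bp jitter; noise peaks are fraction-private and placed on a
  lattice guaranteeing they can never pair across fractions or merge with
  truth; blacklist "artifact" peaks appear in all fractions but lie
  inside the blacklist;
* planted cancer-specific/normal-specific/shared SEs satisfy the support
  rules by construction (including one SE fragmented into two pieces
  10 kb apart in one sample, exercising the stitching rule, and decoy SEs
  present in too few samples);
* correlation peaks sit on contacts inside psi SEs; decoy correlation
  peaks sit inside omega SEs *away from* any contact — so the tests
  verify that contact confirmation, not SE overlap, drives the label;
  two omega SEs carry confirmed peaks only at a target gene's TSS
  (promoter mode);
* boundary genes are planted at exactly 100,000 bp and 100,001 bp from a
  jitter-free SE, and one overlapping gene has mean TPM exactly 1;
* cohort expression follows
  `log2 expr = base + shift·[tumor] + β·activity + γ·purity + noise`,
  with a shared latent "focal activity" factor giving controllable
  coupling targets. Planted triple-validated genes get positive shift and
  β; decoy categories fail exactly one layer each, with the
  co-expression decoys given *negative* β so their failure is
  deterministic rather than probabilistic.

Default scale: 18 + 12 + 6 planted SEs over nine samples, ~116 contact
peaks, ~100 genes, 120 tumor + 20 normal cohort samples, 50 lncRNAs.
These sizes keep a full run — including 1000-iteration permutation tests
and the 10,000-set co-expression null — in a few seconds while leaving
every count large enough to be statistically meaningful.

What the generator does **not** emulate: read-level data and peak-calling
noise (simulation starts at the peak/annotation level), realistic genome
architecture (gene density, GC, repeat structure — placements are
slot-uniform), inter-gene expression covariance beyond the single latent
factor, and cross-cell-type correlation structure in the epigenetic
layer (mark/sign are drawn from a fixed mix). Passing the planted-truth
tests therefore demonstrates that the *logic* of every rule is exact on
inputs of the right shape, not that the pipeline is robust to upstream
calling artifacts in real data.

## Numerical choices

* Percentages are rounded half away from zero at one decimal
  (`round_half_up`), matching how the worked-example shares reproduce
  from their printed numerators and denominators; fold enrichments are
  reported at two decimals.
* Sorting is by (chromosome lexicographic in the C locale, start, end).
* Merging uses strict `gap < max_gap`, with `max_gap = 0` still merging
  touching intervals.
* `iv_shuffle` errors when the lengths cannot fit on their chromosome
  (pigeonhole) and after a bounded retry budget when an exclusion set is
  too dense; both errors name the chromosome.
* Degenerate inputs: empty interval sets flow through every operation;
  an empty correlation table yields zero confirmed peaks and zero psi
  SEs with the pipeline completing; constant purity reduces the partial
  correlation to ordinary Spearman; zero-variance expression vectors
  yield NA correlations that are excluded from set metrics.

## Calibration and validation strategy

The test suite validates the statistical machinery at three levels:
exactness (enumeration oracles for small-sample Mann–Whitney and
Spearman p, a closed-form check for Welch's t, a per-base bitmap oracle
for all interval arithmetic), calibration (both permutation tests on
data generated under independence give empirical p uniform up to add-one
discreteness over 200 seeded runs, with fold enrichment centred on 1 —
note the null generator must place intervals with the same
non-overlapping mechanism the shuffle uses, since the test's null is
defined by that placement distribution), and planted-truth recovery (the
end-to-end run recovers the psi set, class counts, associations and
triple-validated genes exactly at the default noise levels).

## Known limitations

* The psi/omega call is binary at ≥1 bp overlap everywhere; no reciprocal
  overlap fraction or signal weighting is implemented, mirroring the
  procedure it reproduces.
* The permutation null preserves per-chromosome peak counts and lengths
  but not local covariates (GC, mappability, distance constraints);
  enrichment against such structured nulls would require a different
  null model.
* The exact Spearman path is O(n!) and is used only below n = 10;
  mid-rank ties make the enumeration a permutation test rather than the
  classical no-ties lookup.
* Multi-lncRNA ranking treats the correlation-peak table as exchangeable
  across lncRNAs; it does not model per-lncRNA peak abundance.
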