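---
title: "Methods: pseudobulk lncRNA quantification and NB differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudobulk lncRNA quantification and NB differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sclnc` profiles long noncoding RNAs from barcoded single-cell alignments in
four stages: annotation, pseudobulk counting, negative-binomial differential
expression, and genomic-context characterisation. This vignette records the
statistical model, the numerical choices, and the design decisions behind
each stage, together with what the synthetic-data generator does and does
not emulate.

## Annotation and coordinates

Gene models come from GENCODE-dialect GTF (`gene` and `exon` records keyed
by `gene_id`; biotype from `gene_type`, falling back to `gene_biotype`).
Biotypes collapse to three classes: `protein_coding` → coding; `lncRNA` and
the legacy GENCODE values `antisense` and `lincRNA` → lncRNA; everything
else → other. Genes of class "other" stay in the interval index — they can
legitimately compete for reads — but are excluded from lncRNA/coding
reports.

All coordinates, internal and external, are 1-based inclusive: the package
stores intervals in `IRanges`/`GRanges`, whose conventions match the GTF,
so no coordinate translation layer exists to get wrong. A gene's *mature
length* is the size of its exon-interval union — the quantity
strand-specific exon counting actually sees — rather than the genomic span;
span length remains available from the gene table. Mature length is
invariant to exon record order and duplicated exon records by construction
(interval union).

Chromosome naming dialects ("chr1" vs "1") are never silently normalised;
the pipeline's validation pass warns when the annotation and alignment
chromosome sets are disjoint and otherwise leaves names alone.

## Read streaming and pseudobulk partitioning

Reference blocks are derived from the CIGAR: `M`/`=`/`X`/`D` advance the
reference, `N` splits blocks (spliced reads), `I`/`S`/`H`/`P` consume none.
Unmapped, secondary (0x100) and supplementary (0x800) records are skipped
and tallied, as are records below an optional MAPQ floor (default 0 — no
filter, since the original counting protocol states none). Barcodes are
matched exactly against the cluster map (no whitelist logic or error
correction); reads with no barcode, an unknown barcode, or NH > 1
(multimappers) are dropped with per-reason tallies. Every tally is an exact
partition: assigned + dropped = total records, a property the test suite
checks on randomised inputs.

Counting counts *reads* by default. The upstream protocol counts
cluster-level BAMs directly with no deduplication step, so read counting is
the faithful default; `umi_dedup = TRUE` collapses records to unique
(gene, barcode, UMI) triples after assignment for chemistry where that is
preferred.

## Strand-specific competitive assignment

A read's candidate genes are those whose exon union overlaps at least
`min_overlap` (default 1) bp of at least one read block, with strand
compatibility under the `strandness` parameter: `forward` (default —
sense-strand counting) requires gene strand = read strand. One candidate →
assigned; several → ambiguous (discarded, never fractionally split — the
default behaviour of exon-union counters); none but an opposite-strand exon
overlap → `strand_mismatch`; otherwise `no_feature`.

Two deliberate choices:

* **Competition set.** The default run counts coding and lncRNA annotations
  together in one competitive pass, because counting against the lncRNA
  annotation alone misattributes coding-gene reads to overlapping antisense
  lncRNAs whenever strand alone cannot separate them. Counting against
  lncRNAs only — the minimal protocol — is available via
  `filter_biotype(ann, "lncRNA")`; both paths are tested.
* **Strandness is a first-class parameter**, not a constant: whether a
  library's chemistry implies sense or antisense counting is a property of
  the data, so `forward`/`reverse`/`unstranded` are all implemented and
  oracle-tested.

Assignment is validated read-for-read against an independently written
brute-force overlap checker on randomised instances (mixed spliced and
unspliced reads, both strands, all three strandness modes), and satisfies
a strand-flip symmetry: flipping every read and gene strand leaves all
outcomes unchanged.

## Differential expression

The count model is negative binomial with a log link:

* **Size factors** use the median-of-ratios estimator over the genes
  positive in every sample. When no such gene exists the factors are
  undefined and the fit stops with an informative error rather than
  guessing. One property worth stating precisely: size factors are defined
  only up to a common scale, because the geometric-mean reference moves
  with the data. Multiplying one sample's counts by *c* multiplies its size
  factor by *c* **relative to every other sample**; the absolute vector
  rescales by c^(1/n). The tests assert the ratio form, and the 2-sample
  worked example (columns (10, 30) and (20, 60) → factors 0.7071, 1.4142)
  pins the absolute convention.
* **Dispersion** is estimated gene-wise by maximising the Cox–Reid adjusted
  profile likelihood: the plain profile likelihood is biased low because
  the mean coefficients are estimated from the same data, and subtracting
  half the log-determinant of the weighted design information removes the
  leading-order bias. The fit alternates GLM mean updates with 1-D
  optimisation of the dispersion on the log scale until the change is
  below 1e-6 or 20 rounds, floored at 1e-8; a Pearson method-of-moments
  value is the fallback (with a warning) if the optimisation fails. There
  is deliberately **no** empirical-Bayes shrinkage across genes, no LFC
  shrinkage, and no independent filtering beyond the baseMean rule — a
  documented simplification; well-replicated pseudobulk data must carry
  the inference on its own.
* **GLM and Wald test.** Per gene, IRLS with offsets `log s_j`
  (convergence: max coefficient change < 1e-8, at most 100 iterations;
  non-converged genes are flagged and their p-values set undefined).
  `log2FoldChange` is the contrast coefficient / ln 2 with its standard
  error from the observed Fisher information. The Wald statistic is
  referred to **Student's t with residual degrees of freedom** (samples
  minus fitted coefficients), not the normal: with gene-wise dispersions
  and tens of samples, the normal reference is too light-tailed exactly
  where Benjamini–Hochberg digs (genes whose dispersion collapsed by
  chance), and the t reference restores far-tail calibration — the same
  small-sample correction used by modern NB GLM packages. With many
  samples the two references coincide.
* **Filtering and adjustment.** Genes with `baseMean >= 1` (inclusive — the
  source protocol is ambiguous between ≥ and >) are tested;
  Benjamini–Hochberg step-up adjustment; significance at `padj < 0.01`.
  Both thresholds are parameters.
* **Design.** Two one-factor contrasts (cell type; first vs last timepoint)
  are the default rather than one two-factor model, because the analyses
  are reported separately downstream; an optional additive covariate column
  is supported. The replication unit is the pseudobulk sample
  (cluster × timepoint). Fewer than 2 replicates per level warns but does
  not stop: the information is in the data, and hard failure would forbid
  legitimate exploratory runs.

One behaviour users should know about: with median-of-ratios
normalisation, a strongly one-directional DE signal is partially absorbed
into the affected group's size factors (at 10 % of genes planted at +2
log2 units the expected fold-change shrinkage is roughly 0.09 log2 units).
This is a property of the estimator class, not an implementation artifact;
the generator's `direction = "both"` mode plants sign-balanced effects for
composition-neutral benchmarking.

## Genomic context and cis pairs

The gap between two gene spans is 0 when they overlap and
`later.start − earlier.end` otherwise, so adjacent spans have gap 1 and
`gap == 0` is exactly equivalent to overlap. (The off-the-shelf
`IRanges::distance()` maps both overlap and adjacency to 0, which would
make "gap 0 ⇔ overlapping relation" false on a boundary case; the
arithmetic definition keeps the invariant exact.) An lncRNA is
*intragenic* when the gap to its nearest protein-coding gene on the same
chromosome is ≤ 5000 bp — the boundary itself is intragenic — and
*intergenic* otherwise; the window is a parameter. Ties on the gap break
to the lexicographically smallest coding `gene_id`, making the pairing
deterministic. The term "intragenic" follows the upstream protocol's usage
(proximity, not containment); the conventional relation
(`overlapping_sense`/`overlapping_antisense`/`upstream`/`downstream`, with
a signed offset in the coding gene's orientation) is reported alongside so
no information is lost.

Cis pairs take both partners' log2 fold changes from the *same* contrast;
pairs where either gene was untested are dropped and tallied. The
significance filter for the pair table is configurable — lncRNA, coding,
both (default, the strictest reading of the source figure), or none — and
the correlation is the sample Pearson coefficient with the sign-concordant
fraction reported beside it. Fewer than 3 pairs or zero variance in either
coordinate yields an explicit undefined r, never a number.

Distances and PCA use `log2(normalised + 1)`: the +1 pseudocount is a
documented simplification standing in for a variance-stabilising
transform, chosen because it is exact at zero and monotone. PCA centres
genes, projects samples onto right-singular directions, and fixes each
component's sign by making the largest-magnitude loading positive, so
output is deterministic.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: two cell
populations (DA, FP), three timepoints (day16/day30/day60), a configurable
number of upstream clusters per cell type (default 2, giving 6
pseudobulks per cell type), and ~30 cells per cluster × timepoint. Genes
are laid out on toy chromosomes with a placement plan per lncRNA —
antisense inside a host coding gene (gap 0, opposite strand), near (gap
uniform on 1–5000 bp, intragenic by the 5 kb rule), far (6000–50 000 bp,
intergenic) — with 55 kb guard spacing so the planted host is provably the
nearest coding gene. Per cell and gene, read counts are NB
(default dispersion 0.1 across cells; mean ~0.35 reads/cell/gene, lognormal
across genes) with planted log2 fold changes of magnitude 2 on 15 % of
genes per contrast; a planted cell-type effect on an intragenic lncRNA is
shared with its host coding gene (`cis_coupled`), which is what makes
cis-pair correlation positive by construction. Reads (90 bp, single-block
by default; `frac_spliced` plants N-gap junction reads) are placed
uniformly within the gene's exon union on the gene's strand — forward
chemistry — with exact barcodes, `NH:i:1`, and optional UMIs. The same
seed reproduces every output byte-identically.

What the generator does **not** emulate, and therefore what green tests do
not establish about real data: sequencing error and barcode corruption
(the pipeline matches barcodes exactly, so corruption would only exercise
drop tallies, which unit tests cover directly); ambient RNA and doublets;
intronic and intergenic background reads; realistic transcript sequence;
library-size extremes; and annotation errors. Passing tests demonstrate
the pipeline's correctness contracts (assignment, conservation,
calibration, determinism), not robustness to upstream artefacts.

Scale of the shipped defaults (105 genes, 12 pseudobulks, ~18 000 reads;
the DE benchmark uses 500 genes × 20 samples) keeps the full suite around
two minutes; the properties tested are scale-free.

## Known limitations

* Transcript-level (EM) quantification, fractional multi-overlap counting
  and intron/exon ratios are out of scope; counting is gene-level over
  exon unions.
* Likelihood-ratio tests, multi-level contrasts, surrogate-variable/batch
  correction and outlier moderation (Cook's-style) are not implemented.
* The 5 kb rule measures span-to-span gaps; TSS-anchored distances are a
  different convention and would need a different anchor.
* Paired-end fragments are counted by the first-in-pair record's blocks;
  3' tag chemistry is effectively single-end, so mate merging is not
  implemented.
* trans (distal) lncRNA–gene pairing, conservation and coding-potential
  scoring are out of scope.
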