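# sclnc

Cluster-pseudobulk profiling of long noncoding RNAs (lncRNAs) from
barcoded single-cell alignments.

Most single-cell RNA-seq pipelines are tuned to protein-coding genes;
lncRNAs — typically lowly expressed, often antisense to coding genes, and
strand-sensitive by nature — fall through the cracks. `sclnc` implements a
quantification-and-analysis pipeline for lncRNAs that reuses the cell
populations already defined from coding-gene clustering: reads from a
10x-style BAM are partitioned by cell barcode into cluster × timepoint
pseudobulk samples, assigned to genes strand-specifically over exon unions,
and tested for differential expression across cell types (e.g. dopaminergic
neurons vs floor-plate progenitors) and differentiation timepoints with a
negative-binomial Wald model implemented in the package. Downstream tools
characterise the genomic context of each lncRNA — its nearest protein-coding
gene, the 5 kb intragenic rule, cis-pair fold-change correlation — and the
descriptive summaries (strand tallies, mature-length distribution, sample
distance matrix, PCA, MA tables).

## The model

Counts `K[g, j]` for gene *g* in pseudobulk sample *j* are modelled as
negative binomial:

    K[g, j] ~ NB(mean = s_j * q[g, j],  dispersion = alpha_g)
    log(q[g, j]) = x_j' * beta_g            Var = mu + alpha_g * mu^2

* `s_j` — size factors by the median-of-ratios method: the median over
  all-sample-positive genes of `K[g, j] / geomean_g(K[g, .])`.
* `alpha_g` — gene-wise dispersion maximising the Cox–Reid adjusted profile
  likelihood under the design-fitted means (no shrinkage across genes).
* `beta_g` — intercept + two-level contrast (cell type, or timepoint),
  fitted by iteratively reweighted least squares with `log s_j` offsets.
* Wald test: `log2FC / SE` against a t reference with residual degrees of
  freedom; Benjamini–Hochberg adjustment; significance at `padj < 0.01`;
  genes with `baseMean >= 1` tested.

Read-to-gene assignment is competitive and strand-specific ("forward":
gene strand must equal read strand); a read overlapping exon unions of two
compatible genes is discarded as ambiguous, never split. An lncRNA is
*intragenic* when its span lies within 5 kb of (or overlaps) a
protein-coding gene span, else *intergenic*.

## Worked example

The package ships a synthetic-study generator with planted ground truth, so
the whole pipeline runs without external data:

```r
library(sclnc)

cfg <- sim_config(seed = 7)           # 2 cell types x 3 timepoints, planted LFCs
sim <- simulate_study(cfg, "demo")    # writes GTFs, reads.sam, clusters.tsv

ann <- sim$ann
cm  <- build_count_matrix(read_alignments(sim$sam), ann,
                          read_cluster_map(sim$clusters),
                          strandness = "forward")
cm
#> <sclnc_counts> 105 genes x 12 pseudobulk samples; total counts 18310

de <- run_de(cm, contrast = "cell_type", alpha = 0.01)
de
#> <sclnc_de> contrast cell_type: FP vs DA (reference)
#>   105 genes tested (baseMean >= 1 of 105); 15 significant at padj < 0.01

dplyr::arrange(tidy(de), padj)[1:3, 1:7]
#>   gene_id baseMean log2FoldChange lfcSE   stat       pvalue     padj
#> 1 PC0039      66.3          -2.04 0.131 -15.6  0.0000000241  2.53e-6
#> 2 LNC0019     45.6           1.87 0.148  12.7  0.000000175   6.13e-6
#> 3 LNC0025     52.1          -2.29 0.177 -12.9  0.000000143   6.13e-6

ctx <- classify_context(ann, window = 5000)
dplyr::count(ctx, class)
#>   class          n
#> 1 intergenic    10
#> 2 intragenic    35

cis_correlation(cis_pairs(ctx, de, significant = "none"))
#>   pearson_r n_pairs frac_concordant
#> 1     0.670      35           0.571
```

`log2FoldChange` is FP relative to DA (the reference level); `LNC0019` at
+1.87 recovers its planted 4× enrichment in floor-plate progenitors. The
positive cis-pair correlation (r = 0.67 over 35 intragenic lncRNA–coding
pairs) reflects the coupled fold changes the generator plants on
lncRNA/host pairs. Each result type has a plot: `autoplot(de)` (MA plot),
`plot_pca(pca_samples(cm))`, `plot_cis_pairs()`,
`plot_length_distribution()`, `plot_sample_distances()`.

A thin command-line front end covers the same flow
(`inst/cli/sclnc simulate|count|de|context|run`), and `run_pipeline()`
writes every artifact (counts, DE tables, context and pair tables,
distance matrix, PCA, MA tables) as TSV with a checksummed manifest;
reruns on identical inputs are byte-identical.

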