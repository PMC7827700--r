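#' Classify lncRNAs by proximity to protein-coding genes (5 kb rule)
#'
#' For every lncRNA, finds the nearest protein-coding gene on the same
#' chromosome by span gap and classifies the lncRNA as `intragenic` when the
#' gap is at most `window` bp (default 5000), else `intergenic`. The gap
#' between disjoint spans is `later.start - earlier.end` (adjacent spans
#' have gap 1); overlapping spans have gap 0, so `gap_bp == 0` exactly when
#' the relation is an overlapping one. Ties on gap are broken by the
#' lexicographically smallest coding `gene_id`.
#'
#' The relation field records the configuration: `overlapping_sense` /
#' `overlapping_antisense` by strand agreement on overlap, otherwise
#' `upstream` / `downstream` of the coding gene in the coding gene's
#' orientation. `signed_offset` is `-gap_bp` upstream, `+gap_bp` downstream,
#' 0 on overlap.
#'
#' @param ann An `sclnc_annotation` containing both lncRNA and coding genes,
#'   or just the lncRNAs if `coding` is given separately.
#' @param coding Optional `sclnc_annotation` of protein-coding genes;
#'   defaults to `filter_biotype(ann, "coding")`.
#' @param window Proximity window in bp (default 5000).
#' @return Tibble with one row per lncRNA: `lnc_id`, `chrom`, `coding_id`
#'   (NA when no coding gene shares the chromosome), `gap_bp`,
#'   `signed_offset`, `relation`, `class` (`intragenic`/`intergenic`).
#' @export
classify_context <- function(ann, coding = NULL, window = 5000) {
  stopifnot(inherits(ann, "sclnc_annotation"))
  lnc <- filter_biotype(ann, "lncRNA")$genes
  cod <- if (is.null(coding)) filter_biotype(ann, "coding")$genes
         else coding$genes[coding$genes$biotype == "coding", , drop = FALSE]
  if (nrow(lnc) == 0) {
    return(tibble::tibble(lnc_id = character(0), chrom = character(0),
                          coding_id = character(0), gap_bp = numeric(0),
                          signed_offset = numeric(0), relation = character(0),
                          class = character(0)))
  }
  res <- purrr::map_dfr(seq_len(nrow(lnc)), function(i) {
    L <- lnc[i, ]
    C <- cod[cod$chrom == L$chrom, , drop = FALSE]
    if (nrow(C) == 0) {
      return(tibble::tibble(lnc_id = L$gene_id, chrom = L$chrom,
                            coding_id = NA_character_, gap_bp = NA_real_,
                            signed_offset = NA_real_,
                            relation = NA_character_, class = "intergenic"))
    }
    gaps <- span_gap(L$start, L$end, C$start, C$end)
    j <- which(gaps == min(gaps))
    j <- j[order(C$gene_id[j])][1]
    g <- gaps[j]
    rel <- pair_relation(L, C[j, ], g)
    tibble::tibble(
      lnc_id = L$gene_id, chrom = L$chrom, coding_id = C$gene_id[j],
      gap_bp = g, signed_offset = rel$offset, relation = rel$relation,
      class = if (g <= window) "intragenic" else "intergenic"
    )
  })
  res
}

# gap between 1-based inclusive spans: 0 on overlap, later.start - earlier.end
# otherwise (adjacent spans have gap 1)
span_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1 - e2, s2 - e1))
}

pair_relation <- function(L, C, gap) {
  if (gap == 0) {
    rel <- if (L$strand == C$strand) "overlapping_sense" else "overlapping_antisense"
    return(list(relation = rel, offset = 0))
  }
  lnc_before <- L$end < C$start
  upstream <- (C$strand == "+" && lnc_before) || (C$strand == "-" && !lnc_before)
  list(relation = if (upstream) "upstream" else "downstream",
       offset = if (upstream) -gap else gap)
}

#' Build cis lncRNA/coding pairs with shared-contrast fold changes
#'
#' Joins the intragenic lncRNA-coding pairs from [classify_context()] with
#' the log2 fold changes of one differential-expression contrast, for both
#' partners. Pairs where either partner was not tested are dropped and
#' tallied in the `"dropped"` attribute; an optional significance filter
#' (adjusted p below the DE object's alpha) can be applied to the lncRNA,
#' the coding gene, or both.
#'
#' @param context Tibble from [classify_context()].
#' @param de An `sclnc_de` fit on a matrix containing both biotypes.
#' @param significant `"both"` (default), `"lnc"`, `"coding"` or `"none"`.
#' @return Tibble: `lnc_id`, `coding_id`, `gap_bp`, `relation`, `lnc_lfc`,
#'   `coding_lfc`, with attribute `"dropped"` = number of intragenic pairs
#'   lost to the tested/significance filters.
#' @export
cis_pairs <- function(context, de,
                      significant = c("both", "lnc", "coding", "none")) {
  significant <- match.arg(significant)
  stopifnot(inherits(de, "sclnc_de"))
  tab <- tidy(de)
  intra <- context[context$class == "intragenic" & !is.na(context$coding_id), ,
                   drop = FALSE]
  pairs <- dplyr::inner_join(
    dplyr::inner_join(
      intra,
      dplyr::select(tab, lnc_id = "gene_id", lnc_lfc = "log2FoldChange",
                    lnc_sig = "significant"),
      by = "lnc_id"
    ),
    dplyr::select(tab, coding_id = "gene_id", coding_lfc = "log2FoldChange",
                  coding_sig = "significant"),
    by = "coding_id"
  )
  pairs <- pairs[!is.na(pairs$lnc_lfc) & !is.na(pairs$coding_lfc), , drop = FALSE]
  keep <- switch(significant,
    both = pairs$lnc_sig & pairs$coding_sig,
    lnc = pairs$lnc_sig,
    coding = pairs$coding_sig,
    none = rep(TRUE, nrow(pairs))
  )
  out <- dplyr::select(pairs[keep, , drop = FALSE],
                       "lnc_id", "coding_id", "gap_bp", "relation",
                       "lnc_lfc", "coding_lfc")
  attr(out, "dropped") <- nrow(intra) - nrow(out)
  out
}

#' Pearson correlation of cis-pair fold changes
#'
#' @param pairs Tibble with columns `lnc_lfc` and `coding_lfc` (e.g. from
#'   [cis_pairs()]), one row per lncRNA-coding pair.
#' @return One-row tibble: `pearson_r`, `n_pairs`, `frac_concordant`
#'   (fraction of pairs whose fold changes share a sign). `pearson_r` is NA
#'   when fewer than 3 pairs are available or either coordinate has zero
#'   variance.
#' @export
cis_correlation <- function(pairs) {
  x <- pairs$lnc_lfc
  y <- pairs$coding_lfc
  n <- length(x)
  r <- NA_real_
  if (n >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
    r <- stats::cor(x, y, method = "pearson")
  } else if (n >= 3) {
    message("cis_correlation: zero variance in a coordinate; r undefined")
  }
  tibble::tibble(
    pearson_r = r, n_pairs = n,
    frac_concordant = if (n > 0) mean(sign(x) == sign(y) & x != 0) else NA_real_
  )
}

#' Tally expressed genes by strand
#'
#' @param genes Tibble with a `strand` column (`+` sense, `-` antisense),
#'   typically the expressed lncRNAs.
#' @return One-row tibble: `n_sense`, `n_antisense`, `n_total`.
#' @export
strand_tally <- function(genes) {
  s <- genes$strand
  tibble::tibble(n_sense = sum(s == "+"), n_antisense = sum(s == "-"),
                 n_total = length(s))
}

#' Genes passing the expression filter
#'
#' @param object `sclnc_counts` object.
#' @param min_base_mean baseMean threshold, inclusive (default 1).
#' @return The gene tibble restricted to genes with
#'   `baseMean >= min_base_mean`, with a `baseMean` column appended.
#' @export
expressed_genes <- function(object, min_base_mean = 1) {
  stopifnot(inherits(object, "sclnc_counts"))
  bm <- base_means(object)
  g <- object$genes
  g$baseMean <- unname(bm[g$gene_id])
  g[g$baseMean >= min_base_mean, , drop = FALSE]
}

#' Mature-length histogram of expressed lncRNAs
#'
#' @param lengths Numeric vector of exon-union (mature) lengths in bp, or a
#'   gene tibble with a `mature_length` column.
#' @param breaks Right-open bin edges; the last bin is
#'   `[breaks[n], Inf)` when the final edge is finite. Default bins bracket
#'   the typical lncRNA range.
#' @return Tibble: `lower`, `upper`, `n`; `sum(n)` equals the input size.
#' @export
length_distribution <- function(lengths,
                                breaks = c(0, 300, 500, 1000, 2500, 5000,
                                           10000, Inf)) {
  if (is.data.frame(lengths)) lengths <- lengths$mature_length
  breaks <- sort(unique(c(breaks, Inf)))
  bins <- cut(lengths, breaks = breaks, right = FALSE)
  tibble::tibble(
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    n = as.integer(table(bins))
  )
}

#' Euclidean distance between samples on log2 normalised counts
#'
#' @param object `sclnc_counts` or count matrix.
#' @param sf Size factors (computed if `NULL`).
#' @return Symmetric numeric matrix of Euclidean distances between the
#'   `log2(normalised + 1)` expression profiles of each pair of samples.
#' @export
sample_distances <- function(object, sf = NULL) {
  lg <- log_normalized_counts(object, sf)
  as.matrix(stats::dist(t(lg), method = "euclidean"))
}

#' PCA of samples on log2 normalised counts
#'
#' Genes are centred (per-gene mean subtracted) on the
#' `log2(normalised + 1)` scale and samples are projected onto the top
#' principal directions. The sign of each component is fixed by convention:
#' the largest-magnitude gene loading is made positive, so output is
#' deterministic.
#'
#' @param object `sclnc_counts` or count matrix.
#' @param n_components Number of components (default 2; truncated with a
#'   warning when fewer are available).
#' @param sf Size factors (computed if `NULL`).
#' @param metadata Optional sample tibble joined onto the coordinates
#'   (defaults to the object's sample table when available).
#' @return Object of class `sclnc_pca`: list with `coords` (tibble:
#'   `sample_id`, `PC1`, ..., plus metadata columns) and `var_explained`
#'   (fractions in `[0, 1]`, non-increasing).
#' @export
pca_samples <- function(object, n_components = 2, sf = NULL, metadata = NULL) {
  lg <- log_normalized_counts(object, sf)
  if (is.null(metadata) && inherits(object, "sclnc_counts")) {
    metadata <- object$samples
  }
  n_avail <- min(ncol(lg) - 1L, nrow(lg))
  if (n_components > n_avail) {
    warning("only ", n_avail, " principal component(s) available; truncating",
            call. = FALSE)
    n_components <- n_avail
  }
  pc <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- pc$rotation[, k, drop = FALSE]
  scores <- pc$x[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  coords <- tibble::as_tibble(scores)
  coords <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(lg)), coords)
  if (!is.null(metadata)) {
    coords <- dplyr::left_join(coords, tibble::as_tibble(metadata),
                               by = "sample_id")
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coords = coords, var_explained = ve[k], rotation = rot),
            class = "sclnc_pca")
}

#' @export
print.sclnc_pca <- function(x, ...) {
  cat("<sclnc_pca> ", nrow(x$coords), " samples, ",
      length(x$var_explained), " components (",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @method tidy sclnc_pca
#' @export
tidy.sclnc_pca <- function(x, ...) x$coords

#' MA table of a differential-expression result
#'
#' @param de An `sclnc_de` object.
#' @return Tibble with one row per tested gene: `gene_id`,
#'   `log2_base_mean`, `log2FoldChange`, `significant`.
#' @export
ma_table <- function(de) {
  stopifnot(inherits(de, "sclnc_de"))
  tab <- tidy(de)
  tibble::tibble(
    gene_id = tab$gene_id,
    log2_base_mean = log2(tab$baseMean),
    log2FoldChange = tab$log2FoldChange,
    significant = tab$significant
  )
}
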