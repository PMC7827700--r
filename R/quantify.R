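#' Assign reads to genes over exon unions, strand-specifically
#'
#' For each read, candidate genes are those whose exon union overlaps at
#' least `min_overlap` bp of at least one of the read's reference blocks and
#' whose strand is compatible with the read under `strandness`:
#' `"forward"` requires gene strand == read strand (sense counting, the
#' default for 10x 3' chemistry as counted here), `"reverse"` the opposite,
#' `"unstranded"` ignores strand. A read with exactly one candidate is
#' `assigned`; two or more, `ambiguous` (discarded, never split); none, but
#' with an exon overlap on the incompatible strand, `strand_mismatch`;
#' otherwise `no_feature`.
#'
#' @param reads Tibble of reads ([read_alignments()] / [partition_reads()]).
#' @param ann An `sclnc_annotation`; all genes in it compete for reads, so
#'   pass a merged coding+lncRNA annotation for competitive assignment or
#'   `filter_biotype(ann, "lncRNA")` to count against lncRNAs alone.
#' @param strandness `"forward"`, `"reverse"` or `"unstranded"`.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `reads` with columns `outcome` (factor: `assigned`, `ambiguous`,
#'   `no_feature`, `strand_mismatch`) and `gene_id` (NA unless assigned).
#' @export
assign_reads <- function(reads, ann,
                         strandness = c("forward", "reverse", "unstranded"),
                         min_overlap = 1L) {
  strandness <- match.arg(strandness)
  stopifnot(inherits(ann, "sclnc_annotation"), is.data.frame(reads))
  n <- nrow(reads)
  out <- reads
  out$outcome <- factor(rep("no_feature", n),
                        levels = c("assigned", "ambiguous", "no_feature",
                                   "strand_mismatch"))
  out$gene_id <- rep(NA_character_, n)
  if (n == 0) return(out)

  nb <- vapply(reads$blocks, nrow, integer(1))
  stopifnot(all(nb >= 1))
  block_gr <- GenomicRanges::GRanges(
    rep(reads$chrom, nb),
    IRanges::IRanges(
      unlist(lapply(reads$blocks, function(b) b[, 1])),
      unlist(lapply(reads$blocks, function(b) b[, 2]))
    )
  )
  read_of_block <- rep(seq_len(n), nb)

  # disjoint seqlevels are legitimate here (dialect checks are reported by
  # the pipeline validation pass, not per-read)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(block_gr, ann$exons,
                                minoverlap = min_overlap,
                                ignore.strand = TRUE)
  )
  if (length(hits) == 0) return(out)
  ri <- read_of_block[S4Vectors::queryHits(hits)]
  gi <- S4Vectors::mcols(ann$exons)$gene_id[S4Vectors::subjectHits(hits)]
  gstrand <- as.character(GenomicRanges::strand(ann$exons))[S4Vectors::subjectHits(hits)]
  same <- gstrand == reads$strand[ri]
  compatible <- switch(strandness,
    forward = same, reverse = !same, unstranded = rep(TRUE, length(same)))

  ov <- tibble::tibble(read = ri, gene = gi, compatible = compatible)
  ov <- dplyr::distinct(ov)
  cand <- dplyr::summarise(
    dplyr::group_by(ov, .data$read),
    n_cand = sum(.data$compatible),
    n_other = dplyr::n() - sum(.data$compatible),
    gene = if (sum(.data$compatible) == 1) .data$gene[.data$compatible][1]
           else NA_character_,
    .groups = "drop"
  )
  oc <- rep("no_feature", n)
  oc[cand$read[cand$n_cand == 1]] <- "assigned"
  oc[cand$read[cand$n_cand >= 2]] <- "ambiguous"
  if (strandness != "unstranded") {
    sm <- cand$read[cand$n_cand == 0 & cand$n_other > 0]
    oc[sm] <- "strand_mismatch"
  }
  out$outcome <- factor(oc, levels = levels(out$outcome))
  out$gene_id[cand$read] <- cand$gene
  out
}

#' Count assigned reads per gene for one read set
#'
#' @param reads Tibble of reads.
#' @param ann An `sclnc_annotation`.
#' @inheritParams assign_reads
#' @return Tibble with one row per annotation gene (`gene_id`, `count`,
#'   zero-count genes retained) and an attribute `"outcome_tally"` giving
#'   the number of reads per assignment outcome; outcome counts sum to the
#'   number of input reads and `sum(count)` equals the `assigned` tally.
#' @export
count_reads <- function(reads, ann,
                        strandness = c("forward", "reverse", "unstranded"),
                        min_overlap = 1L) {
  strandness <- match.arg(strandness)
  asg <- assign_reads(reads, ann, strandness, min_overlap)
  counts <- tibble::tibble(
    gene_id = sort(ann$genes$gene_id),
    count = as.integer(table(factor(asg$gene_id[asg$outcome == "assigned"],
                                    levels = sort(ann$genes$gene_id))))
  )
  attr(counts, "outcome_tally") <- dplyr::count(
    tibble::tibble(outcome = asg$outcome), .data$outcome, name = "n",
    .drop = FALSE
  )
  counts
}

#' Build the pseudobulk count matrix
#'
#' Partitions reads by cluster, assigns them to genes strand-specifically,
#' optionally collapses UMI duplicates, and tabulates counts per
#' (gene, pseudobulk sample). Gene and sample ordering is lexicographic and
#' deterministic; genes with zero total counts are retained.
#'
#' @param reads Tibble from [read_alignments()].
#' @param ann An `sclnc_annotation` (typically merged coding + lncRNA).
#' @param cmap Cluster map tibble.
#' @inheritParams assign_reads
#' @param umi_dedup If `TRUE`, collapse records to unique
#'   (gene, barcode, UMI) triples after assignment; default `FALSE`, i.e.
#'   count reads.
#' @param drop_multimapped Drop NH > 1 records (default `TRUE`).
#' @return An object of class `sclnc_counts`: list with `counts`
#'   (integer matrix, genes x samples), `genes` (annotation gene tibble),
#'   `samples` (tibble: `sample_id`, `cluster`, `cell_type`, `timepoint`),
#'   `tallies` (per-sample assignment outcome tallies) and
#'   `partition` (the partition summary).
#' @export
build_count_matrix <- function(reads, ann, cmap,
                               strandness = c("forward", "reverse", "unstranded"),
                               min_overlap = 1L, umi_dedup = FALSE,
                               drop_multimapped = TRUE) {
  strandness <- match.arg(strandness)
  routed <- partition_reads(reads, cmap, drop_multimapped = drop_multimapped)
  psum <- partition_summary(routed)
  asg <- assign_reads(routed, ann, strandness, min_overlap)

  samples <- dplyr::arrange(
    dplyr::distinct(cmap[, c("sample_id", "cluster", "cell_type", "timepoint")]),
    .data$sample_id
  )
  if (anyDuplicated(samples$sample_id)) {
    stop("sample name collision in cluster map", call. = FALSE)
  }
  gene_ids <- sort(ann$genes$gene_id)

  hit <- asg[asg$outcome == "assigned", , drop = FALSE]
  if (umi_dedup) {
    has_umi <- !is.na(hit$umi)
    hit <- dplyr::bind_rows(
      hit[!has_umi, , drop = FALSE],
      dplyr::distinct(hit[has_umi, , drop = FALSE],
                      .data$gene_id, .data$barcode, .data$umi,
                      .keep_all = TRUE)
    )
  }
  counts <- table(factor(hit$gene_id, levels = gene_ids),
                  factor(hit$sample_id, levels = samples$sample_id))
  counts <- matrix(as.integer(counts), nrow = length(gene_ids),
                   dimnames = list(gene_ids, samples$sample_id))
  tallies <- dplyr::count(
    tibble::tibble(sample_id = asg$sample_id, outcome = asg$outcome),
    .data$sample_id, .data$outcome, name = "n", .drop = FALSE
  )
  genes <- dplyr::arrange(ann$genes, .data$gene_id)
  new_sclnc_counts(counts, genes, samples, tallies, psum)
}

new_sclnc_counts <- function(counts, genes, samples, tallies = NULL,
                             partition = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            nrow(counts) == nrow(genes), ncol(counts) == nrow(samples))
  structure(list(counts = counts, genes = genes, samples = samples,
                 tallies = tallies, partition = partition),
            class = "sclnc_counts")
}

#' Assemble an `sclnc_counts` object from a plain matrix
#'
#' Convenience constructor for count matrices that did not come from
#' [build_count_matrix()] (e.g. simulated pseudobulk counts). Rows and
#' columns are reordered lexicographically.
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param samples Tibble with `sample_id` matching `colnames(counts)` plus
#'   any design columns (`cell_type`, `timepoint`, ...).
#' @param genes Optional gene tibble with `gene_id` matching
#'   `rownames(counts)`; defaults to a minimal one.
#' @return An `sclnc_counts` object.
#' @export
count_matrix <- function(counts, samples, genes = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  samples <- tibble::as_tibble(samples)
  stopifnot(setequal(samples$sample_id, colnames(counts)))
  if (anyDuplicated(samples$sample_id)) {
    stop("sample name collision", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene_id = rownames(counts))
  }
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$gene_id)
  samples <- dplyr::arrange(samples, .data$sample_id)
  counts <- counts[genes$gene_id, samples$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  new_sclnc_counts(counts, genes, samples)
}

#' @export
print.sclnc_counts <- function(x, ...) {
  cat("<sclnc_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " pseudobulk samples; total counts ", sum(x$counts), "\n", sep = "")
  invisible(x)
}

#' @export
dim.sclnc_counts <- function(x) dim(x$counts)

#' @export
as.matrix.sclnc_counts <- function(x, ...) x$counts

#' Tidy a count matrix into long form
#'
#' @param x An `sclnc_counts` object.
#' @param ... Unused.
#' @return Long tibble: `gene_id`, `sample_id`, `count`, joined with sample
#'   metadata.
#' @method tidy sclnc_counts
#' @export
tidy.sclnc_counts <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Write a count matrix to TSV
#'
#' @param x An `sclnc_counts` object.
#' @param path Output TSV path (genes x samples, `gene_id` first column).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "sclnc_counts"))
  df <- tibble::as_tibble(x$counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
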