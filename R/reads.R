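#' Load a barcode-to-cluster assignment table
#'
#' Reads the TSV that maps each cell barcode to its cluster and timepoint
#' (as produced upstream by clustering on protein-coding genes). Every
#' `(cluster, timepoint)` pair defines one pseudobulk sample.
#'
#' @param path TSV file with header columns `barcode`, `cluster`,
#'   `timepoint`, and optionally `cell_type` (defaults to the cluster label
#'   with any `.suffix` replicate tag stripped).
#' @return A tibble with columns `barcode`, `cluster`, `timepoint`,
#'   `cell_type`, `sample_id` (`cluster_timepoint`), one row per barcode.
#'   Exactly duplicated rows collapse to one; a barcode mapped to two
#'   different assignments is an error.
#' @export
read_cluster_map <- function(path) {
  cm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cluster_map(cm)
}

#' Validate a barcode-to-cluster assignment tibble
#'
#' @param cm Data frame with columns `barcode`, `cluster`, `timepoint`
#'   (and optionally `cell_type`).
#' @return The validated tibble with a `sample_id` column appended.
#' @export
cluster_map <- function(cm) {
  cm <- tibble::as_tibble(cm)
  req <- c("barcode", "cluster", "timepoint")
  miss <- setdiff(req, names(cm))
  if (length(miss) > 0) {
    stop("cluster map is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cm <- dplyr::mutate(cm, dplyr::across(dplyr::all_of(req), as.character))
  if (!"cell_type" %in% names(cm)) {
    cm$cell_type <- sub("\\..*$", "", cm$cluster)
  }
  cm <- dplyr::distinct(cm)
  dup <- cm$barcode[duplicated(cm$barcode)]
  if (length(dup) > 0) {
    stop("barcode(s) with conflicting cluster assignments: ",
         paste(utils::head(unique(dup), 5), collapse = ", "), call. = FALSE)
  }
  cm$sample_id <- paste(cm$cluster, cm$timepoint, sep = "_")
  cm
}

#' Read barcoded alignments from SAM/BAM
#'
#' Streams a SAM or BAM file into a tibble of mapped, primary,
#' non-supplementary alignment records with CIGAR-derived reference blocks.
#' Unmapped, secondary (flag 0x100) and supplementary (0x800) records are
#' skipped and tallied; the tallies feed the partition summary so that
#' record conservation holds end to end.
#'
#' Reference blocks follow the CIGAR: `M`/`=`/`X`/`D` advance the reference,
#' `N` splits a read into separate blocks, `I`/`S`/`H`/`P` consume no
#' reference. Blocks are 1-based inclusive intervals.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @param barcode_tag SAM tag holding the cell barcode (default `"CB"`).
#'   Exact string match downstream; no barcode correction.
#' @param umi_tag SAM tag holding the UMI (default `"UB"`).
#' @param min_mapq Minimum mapping quality; records below it are dropped and
#'   tallied as `low_mapq`. Default 0 (no filter).
#' @return A tibble of class `sclnc_reads` with columns `read_id`, `chrom`,
#'   `strand`, `start`, `end`, `blocks` (list of 2-column start/end integer
#'   matrices), `barcode`, `umi`, `nh`, `flag`, `mapq`, plus an attribute
#'   `"stream_tally"`: a tibble of dropped-record counts by reason.
#' @export
read_alignments <- function(path, barcode_tag = "CB", umi_tag = "UB",
                            min_mapq = 0) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar")
  p <- Rsamtools::ScanBamParam(what = what, tag = c(barcode_tag, umi_tag, "NH"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]

  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) != 0L
  sec_sup <- bitwAnd(flag, bitwOr(256L, 2048L)) != 0L & !unmapped
  low_mapq <- !unmapped & !sec_sup & !is.na(res$mapq) & res$mapq < min_mapq
  keep <- !(unmapped | sec_sup | low_mapq)

  cig <- res$cigar[keep]
  bad <- grepl("[^0-9MIDNSHP=X]", cig)
  if (any(bad)) {
    stop("CIGAR with unknown operation for read ",
         res$qname[keep][which(bad)[1]], call. = FALSE)
  }
  blocks_rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = res$pos[keep], ops = c("M", "=", "X", "D"), reduce.ranges = TRUE
  )
  blocks <- lapply(seq_along(blocks_rl), function(i) {
    r <- blocks_rl[[i]]
    cbind(start = IRanges::start(r), end = IRanges::end(r))
  })

  tag_or_na <- function(tg, n) {
    v <- res$tag[[tg]]
    if (is.null(v)) rep(NA, n) else v
  }
  n_all <- length(flag)
  reads <- tibble::tibble(
    read_id = res$qname[keep],
    chrom = as.character(res$rname[keep]),
    strand = as.character(res$strand[keep]),
    start = vapply(blocks, function(b) b[1, 1], numeric(1)),
    end = vapply(blocks, function(b) b[nrow(b), 2], numeric(1)),
    blocks = blocks,
    barcode = as.character(tag_or_na(barcode_tag, n_all))[keep],
    umi = as.character(tag_or_na(umi_tag, n_all))[keep],
    nh = as.integer(tag_or_na("NH", n_all))[keep],
    flag = flag[keep],
    mapq = res$mapq[keep]
  )
  tally <- tibble::tibble(
    reason = c("unmapped", "secondary_or_supplementary", "low_mapq"),
    n = c(sum(unmapped), sum(sec_sup), sum(low_mapq))
  )
  attr(reads, "stream_tally") <- tally
  class(reads) <- c("sclnc_reads", class(reads))
  reads
}

#' Partition reads into pseudobulk samples by cell barcode
#'
#' Routes each read to the pseudobulk sample of its barcode. Reads with no
#' barcode tag, with a barcode absent from the cluster map, or with NH > 1
#' (multimappers) are dropped and tallied. The returned summary also carries
#' forward the stream-level tallies (unmapped, secondary/supplementary) of
#' [read_alignments()] so that `assigned + dropped = total input records`.
#'
#' @param reads Tibble from [read_alignments()].
#' @param cmap Cluster map tibble from [read_cluster_map()] /
#'   [cluster_map()].
#' @param drop_multimapped Drop reads with NH tag > 1 (default `TRUE`).
#' @return The subset of `reads` that was routed, with `sample_id`,
#'   `cluster`, `cell_type` and `timepoint` columns appended, and an
#'   attribute `"partition_summary"` (see [partition_summary()]).
#' @export
partition_reads <- function(reads, cmap, drop_multimapped = TRUE) {
  stopifnot(is.data.frame(reads), is.data.frame(cmap))
  multi <- if (drop_multimapped) !is.na(reads$nh) & reads$nh > 1 else
    rep(FALSE, nrow(reads))
  no_bc <- !multi & is.na(reads$barcode)
  idx <- match(reads$barcode, cmap$barcode)
  unk <- !multi & !no_bc & is.na(idx)
  keep <- !(multi | no_bc | unk)

  out <- reads[keep, , drop = FALSE]
  m <- idx[keep]
  out$sample_id <- cmap$sample_id[m]
  out$cluster <- cmap$cluster[m]
  out$cell_type <- cmap$cell_type[m]
  out$timepoint <- cmap$timepoint[m]

  stream <- attr(reads, "stream_tally")
  if (is.null(stream)) {
    stream <- tibble::tibble(reason = character(0), n = integer(0))
  }
  summary <- list(
    assigned = dplyr::count(out, .data$sample_id, name = "n"),
    dropped = dplyr::bind_rows(
      stream,
      tibble::tibble(
        reason = c("multimapped", "no_barcode", "unassigned_barcode"),
        n = c(sum(multi), sum(no_bc), sum(unk))
      )
    ),
    total_records = nrow(reads) + sum(stream$n)
  )
  attr(out, "partition_summary") <- summary
  attr(out, "stream_tally") <- NULL
  out
}

#' Partition summary of a read set
#'
#' @param reads Result of [partition_reads()].
#' @return A list with `assigned` (tibble of per-sample routed read counts),
#'   `dropped` (tibble of counts by drop reason, including stream-level
#'   skips) and `total_records` (all records seen, so that
#'   `sum(assigned$n) + sum(dropped$n) == total_records`).
#' @export
partition_summary <- function(reads) {
  s <- attr(reads, "partition_summary")
  if (is.null(s)) stop("no partition summary: run partition_reads() first",
                       call. = FALSE)
  s
}
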