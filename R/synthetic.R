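#' Configuration for the synthetic study generator
#'
#' Defines a fully specified toy single-cell study mirroring the real
#' design: two cell populations (dopaminergic neurons `DA` and floor-plate
#' progenitors `FP`) sampled at three differentiation timepoints (`day16`,
#' `day30`, `day60`), with protein-coding and lncRNA genes laid out on toy
#' chromosomes at controlled distances and per-cell NB-distributed
#' expression with planted log2 fold changes.
#'
#' Each lncRNA follows a placement plan: `overlapping_antisense` (inside a
#' host coding gene's span on the opposite strand, gap 0), `near` (gap
#' drawn uniformly from 1-5000 bp, i.e. intragenic under the 5 kb rule) or
#' `far` (gap 6000-50000 bp, intergenic). Generous guard spacing guarantees
#' the planted host is the true nearest coding gene.
#'
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param n_coding,n_lnc Number of protein-coding / lncRNA genes.
#' @param relation_probs Probabilities of the three placement plans, in the
#'   order antisense, near, far.
#' @param n_chroms Number of toy chromosomes.
#' @param cell_types,timepoints Group labels of the study design.
#' @param clusters_per_type Upstream clusters per cell type (pseudobulk
#'   replicates per cell type and timepoint).
#' @param cells_per_cluster Cells per (cluster, timepoint).
#' @param mean_reads_per_cell Average per-gene per-cell read count before
#'   fold changes (baseline drawn per gene around this value).
#' @param dispersion Per-cell NB dispersion.
#' @param frac_de_celltype,frac_de_time Fractions of genes with a planted
#'   cell-type / timepoint effect.
#' @param lfc Magnitude of planted log2 fold changes.
#' @param cis_coupled If `TRUE` (default), a planted cell-type effect on an
#'   intragenic lncRNA is shared by its host coding gene, so cis pairs are
#'   positively correlated by construction.
#' @param read_length Read length in bp; genes are sized to fit it.
#' @param frac_spliced Fraction of reads planted as spliced (two blocks
#'   separated by an N gap) for multi-exon genes; default 0.
#' @param with_umi Emit a UB tag per read (default `FALSE`: the default
#'   counting mode counts reads, not UMIs).
#' @return A list of class `sclnc_sim_config`.
#' @export
sim_config <- function(seed,
                       n_coding = 60, n_lnc = 45,
                       relation_probs = c(antisense = 0.25, near = 0.4,
                                          far = 0.35),
                       n_chroms = 2,
                       cell_types = c("DA", "FP"),
                       timepoints = c("day16", "day30", "day60"),
                       clusters_per_type = 2,
                       cells_per_cluster = 30,
                       mean_reads_per_cell = 0.35,
                       dispersion = 0.1,
                       frac_de_celltype = 0.15,
                       frac_de_time = 0.15,
                       lfc = 2,
                       cis_coupled = TRUE,
                       read_length = 90,
                       frac_spliced = 0,
                       with_umi = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_coding >= n_lnc, n_lnc >= 1,
            length(cell_types) == 2, length(timepoints) >= 1,
            cells_per_cluster >= 1, dispersion > 0, read_length >= 20)
  cfg <- as.list(environment())
  cfg$relation_probs <- relation_probs / sum(relation_probs)
  class(cfg) <- "sclnc_sim_config"
  cfg
}

#' Simulate a toy genome annotation with planted genomic relations
#'
#' Lays out coding genes and lncRNAs on toy chromosomes per the placement
#' plan in `cfg` (see [sim_config()]), with 1-3 exons per gene, and returns
#' the merged annotation together with the ground-truth relations. With
#' `dir` set, also writes `coding.gtf` and `lncrna.gtf`; output is
#' byte-identical for the same seed.
#'
#' @param cfg An `sclnc_sim_config`.
#' @param dir Optional output directory for the GTF files.
#' @return List: `ann` (merged `sclnc_annotation`), `relations` (tibble:
#'   `lnc_id`, `host_id`, `plan`, `planted_gap`), and with `dir` the paths
#'   `coding_gtf`, `lnc_gtf`.
#' @export
simulate_annotation <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sclnc_sim_config"))
  set.seed(cfg$seed)
  guard <- 55000L
  rl <- cfg$read_length
  plans <- sample(names(cfg$relation_probs), cfg$n_lnc, replace = TRUE,
                  prob = cfg$relation_probs)
  chrom_of <- rep(paste0("chr", seq_len(cfg$n_chroms)),
                  length.out = cfg$n_lnc + (cfg$n_coding - cfg$n_lnc))
  cursor <- stats::setNames(rep(10000L, cfg$n_chroms),
                            paste0("chr", seq_len(cfg$n_chroms)))
  genes <- list()
  exons <- list()
  rel <- list()

  add_gene <- function(id, chrom, strand, start, len, biotype, n_ex) {
    end <- start + len - 1L
    ex <- make_exons(start, end, n_ex, min_exon = 3L * rl)
    genes[[length(genes) + 1]] <<- tibble::tibble(
      gene_id = id, chrom = chrom, strand = strand,
      start = start, end = end, biotype = biotype
    )
    exons[[length(exons) + 1]] <<- tibble::tibble(
      gene_id = id, start = ex$start, end = ex$end
    )
    end
  }

  for (i in seq_len(cfg$n_lnc)) {
    chrom <- chrom_of[i]
    host_id <- sprintf("PC%04d", i)
    lnc_id <- sprintf("LNC%04d", i)
    host_strand <- sample(c("+", "-"), 1)
    host_len <- sample(4000:12000, 1)
    host_start <- cursor[[chrom]]
    host_end <- add_gene(host_id, chrom, host_strand, host_start, host_len,
                         "coding", sample(1:3, 1))
    lnc_len <- min(round(stats::rlnorm(1, log(900), 0.6)) + 3L * rl,
                   host_len - 200L)
    lnc_len <- max(lnc_len, 3L * rl)
    plan <- plans[i]
    if (plan == "antisense") {
      gap <- 0L
      lnc_start <- host_start + sample.int(host_len - lnc_len, 1)
      lnc_strand <- setdiff(c("+", "-"), host_strand)
    } else {
      gap <- if (plan == "near") sample.int(5000L, 1) else sample(6000:50000, 1)
      lnc_start <- host_end + gap
      lnc_strand <- sample(c("+", "-"), 1)
    }
    lnc_end <- add_gene(lnc_id, chrom, lnc_strand, as.integer(lnc_start),
                        as.integer(lnc_len), "lncRNA",
                        sample(1:2, 1, prob = c(0.7, 0.3)))
    rel[[i]] <- tibble::tibble(lnc_id = lnc_id, host_id = host_id,
                               plan = plan, planted_gap = gap)
    cursor[[chrom]] <- as.integer(max(host_end, lnc_end) + guard)
  }
  for (k in seq_len(cfg$n_coding - cfg$n_lnc)) {
    chrom <- chrom_of[cfg$n_lnc + k]
    id <- sprintf("PC%04d", cfg$n_lnc + k)
    len <- sample(4000:12000, 1)
    end <- add_gene(id, chrom, sample(c("+", "-"), 1), cursor[[chrom]], len,
                    "coding", sample(1:3, 1))
    cursor[[chrom]] <- as.integer(end + guard)
  }

  genes <- dplyr::bind_rows(genes)
  exons <- dplyr::bind_rows(exons)
  ann <- gene_models(genes, exons)
  out <- list(ann = ann, relations = dplyr::bind_rows(rel),
              chrom_lengths = cursor)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$coding_gtf <- file.path(dir, "coding.gtf")
    out$lnc_gtf <- file.path(dir, "lncrna.gtf")
    write_gtf(filter_biotype(ann, "coding"), out$coding_gtf)
    write_gtf(filter_biotype(ann, "lncRNA"), out$lnc_gtf)
  }
  out
}

# split a span into n_ex exons of at least min_exon bp separated by gaps
make_exons <- function(start, end, n_ex, min_exon, min_intron = 60L) {
  total <- end - start + 1L
  while (n_ex > 1 && total < n_ex * min_exon + (n_ex - 1) * min_intron) {
    n_ex <- n_ex - 1L
  }
  if (n_ex == 1) return(list(start = start, end = end))
  slack <- total - n_ex * min_exon - (n_ex - 1L) * min_intron
  cuts <- sort(sample.int(slack + 1L, 2L * n_ex - 2L, replace = TRUE) - 1L)
  widths <- diff(c(0L, cuts, slack))
  ex_len <- min_exon + widths[seq(1, 2 * n_ex - 1, by = 2)]
  in_len <- min_intron + c(widths[seq(2, 2 * n_ex - 2, by = 2)], 0L)[seq_len(n_ex - 1)]
  s <- integer(n_ex)
  e <- integer(n_ex)
  pos <- start
  for (i in seq_len(n_ex)) {
    s[i] <- pos
    e[i] <- pos + ex_len[i] - 1L
    pos <- e[i] + 1L + if (i < n_ex) in_len[i] else 0L
  }
  e[n_ex] <- end # absorb rounding into the last exon
  list(start = s, end = e)
}

#' Simulate barcoded reads and the cluster map for a toy study
#'
#' For each cell of each cluster and each gene, draws a read count from
#' `NB(mean = baseline x 2^(planted effects), dispersion)` and places each
#' read uniformly within the gene's exon union on the gene's strand
#' (forward chemistry), with `CB` barcode tag and `NH:i:1`. Writes a
#' coordinate-sorted SAM and the barcode-to-cluster TSV; output is
#' byte-identical for the same seed.
#'
#' Planted effects (ground truth in `truth$genes`) are expressed as the
#' log2 fold change of the second alphabetical level versus the first
#' (`FP` vs `DA`; last timepoint vs first, with intermediate timepoints
#' interpolated), matching the sign convention of [run_de()].
#'
#' @param cfg An `sclnc_sim_config`.
#' @param sim_ann Result of [simulate_annotation()] for the same config.
#' @param dir Output directory (created if needed).
#' @return List: `sam`, `clusters` (file paths), `truth` with
#'   `genes` (per-gene baseline and planted LFCs), `routing` (per-read
#'   barcode/gene/sample), `counts` (realised gene x sample matrix of
#'   emitted reads), and `cells` (barcode table).
#' @export
simulate_reads <- function(cfg, sim_ann, dir) {
  stopifnot(inherits(cfg, "sclnc_sim_config"))
  set.seed(cfg$seed + 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- sim_ann$ann
  genes <- ann$genes
  ng <- nrow(genes)

  # planted per-gene effects
  base_mu <- pmin(pmax(stats::rlnorm(ng, log(cfg$mean_reads_per_cell), 0.8),
                       0.02), 10)
  lfc_ct <- rep(0, ng)
  lfc_tp <- rep(0, ng)
  n_ct <- round(cfg$frac_de_celltype * ng)
  n_tp <- round(cfg$frac_de_time * ng)
  ct_idx <- sample.int(ng, n_ct)
  lfc_ct[ct_idx] <- sample(c(-cfg$lfc, cfg$lfc), n_ct, replace = TRUE)
  tp_idx <- sample.int(ng, n_tp)
  lfc_tp[tp_idx] <- sample(c(-cfg$lfc, cfg$lfc), n_tp, replace = TRUE)
  if (isTRUE(cfg$cis_coupled)) {
    rel <- sim_ann$relations
    intra <- rel[rel$plan %in% c("antisense", "near"), , drop = FALSE]
    li <- match(intra$lnc_id, genes$gene_id)
    hi <- match(intra$host_id, genes$gene_id)
    share <- lfc_ct[li] != 0
    lfc_ct[hi[share]] <- lfc_ct[li[share]]
  }
  truth_genes <- tibble::tibble(
    gene_id = genes$gene_id, biotype = genes$biotype, base_mu = base_mu,
    lfc_celltype = lfc_ct, lfc_timepoint = lfc_tp
  )

  # cells
  ct2 <- sort(cfg$cell_types)
  tps <- sort(cfg$timepoints)
  clusters <- tidyr::expand_grid(
    cell_type = ct2, rep = seq_len(cfg$clusters_per_type), timepoint = tps
  )
  clusters$cluster <- paste0(clusters$cell_type, ".", clusters$rep)
  clusters$sample_id <- paste(clusters$cluster, clusters$timepoint, sep = "_")
  cells <- clusters[rep(seq_len(nrow(clusters)), each = cfg$cells_per_cluster), ]
  cells$barcode <- sprintf("BC%05d-1", seq_len(nrow(cells)))

  # per-cell effect multipliers
  tp_frac <- (match(cells$timepoint, tps) - 1) / max(1, length(tps) - 1)
  ct_ind <- as.integer(cells$cell_type == ct2[2]) # 1 for second level
  # mean for gene g in cell c: mu_g * 2^(lfc_ct * (ind - 0.5)) * 2^(lfc_tp * (frac - 0.5))
  n_cells <- nrow(cells)
  exon_by_gene <- split(
    tibble::tibble(start = GenomicRanges::start(ann$exons),
                   end = GenomicRanges::end(ann$exons)),
    S4Vectors::mcols(ann$exons)$gene_id
  )

  recs <- vector("list", ng)
  counts <- matrix(0L, ng, nrow(clusters),
                   dimnames = list(genes$gene_id, clusters$sample_id))
  rid <- 0L
  for (g in seq_len(ng)) {
    mu_c <- base_mu[g] *
      2^(lfc_ct[g] * (ct_ind - 0.5)) *
      2^(lfc_tp[g] * (tp_frac - 0.5))
    k <- stats::rnbinom(n_cells, mu = mu_c, size = 1 / cfg$dispersion)
    tot <- sum(k)
    if (tot == 0) next
    cell_of <- rep(seq_len(n_cells), k)
    ex <- exon_by_gene[[genes$gene_id[g]]]
    placed <- place_reads(tot, ex, cfg$read_length, cfg$frac_spliced)
    ids <- sprintf("r%08d", rid + seq_len(tot))
    rid <- rid + tot
    recs[[g]] <- tibble::tibble(
      read_id = ids, gene_id = genes$gene_id[g],
      chrom = genes$chrom[g], strand = genes$strand[g],
      pos = placed$pos, cigar = placed$cigar,
      barcode = cells$barcode[cell_of],
      sample_id = cells$sample_id[cell_of]
    )
    tab <- table(factor(cells$sample_id[cell_of], levels = clusters$sample_id))
    counts[g, ] <- as.integer(tab)
  }
  reads <- dplyr::bind_rows(recs)
  if (isTRUE(cfg$with_umi)) {
    reads$umi <- vapply(seq_len(nrow(reads)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    }, character(1))
  }

  sam_path <- file.path(dir, "reads.sam")
  clusters_path <- file.path(dir, "clusters.tsv")
  write_sim_sam(reads, sim_ann$chrom_lengths, sam_path)
  readr::write_tsv(
    cells[, c("barcode", "cluster", "timepoint", "cell_type")],
    clusters_path, progress = FALSE
  )
  list(
    sam = sam_path, clusters = clusters_path,
    truth = list(
      genes = truth_genes,
      routing = reads[, c("read_id", "barcode", "gene_id", "sample_id")],
      counts = counts,
      cells = cells
    )
  )
}

# uniform placement of n reads within the exon union; optionally spliced
# two-block reads across adjacent exons
place_reads <- function(n, ex, read_len, frac_spliced) {
  w <- ex$end - ex$start + 1L
  ok <- which(w >= read_len)
  stopifnot(length(ok) > 0)
  pos <- integer(n)
  cigar <- character(n)
  spliced <- if (frac_spliced > 0 && length(ex$start) >= 2) {
    stats::runif(n) < frac_spliced
  } else rep(FALSE, n)
  n_plain <- sum(!spliced)
  if (n_plain > 0) {
    probs <- (w[ok] - read_len + 1)
    ei <- ok[sample.int(length(ok), n_plain, replace = TRUE,
                        prob = probs / sum(probs))]
    off <- floor(stats::runif(n_plain) * (w[ei] - read_len + 1))
    pos[!spliced] <- ex$start[ei] + as.integer(off)
    cigar[!spliced] <- paste0(read_len, "M")
  }
  if (any(spliced)) {
    n_sp <- sum(spliced)
    ji <- sample.int(length(ex$start) - 1L, n_sp, replace = TRUE)
    a <- pmin(pmax(sample.int(read_len - 10L, n_sp, replace = TRUE), 10L),
              w[ji] - 1L)
    a <- pmax(a, read_len - (w[ji + 1L] - 1L))
    a <- pmin(pmax(a, 1L), read_len - 1L)
    b <- read_len - a
    gap <- ex$start[ji + 1L] - ex$end[ji] - 1L
    pos[spliced] <- ex$end[ji] - a + 1L
    cigar[spliced] <- paste0(a, "M", gap, "N", b, "M")
  }
  list(pos = pos, cigar = cigar)
}

write_sim_sam <- function(reads, chrom_lengths, path) {
  chroms <- sort(names(chrom_lengths))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      as.integer(chrom_lengths[chroms]) + 10000L))
  ord <- order(match(reads$chrom, chroms), reads$pos, reads$read_id,
               method = "radix")
  r <- reads[ord, , drop = FALSE]
  tags <- sprintf("CB:Z:%s\tNH:i:1", r$barcode)
  if ("umi" %in% names(r)) tags <- paste0(tags, sprintf("\tUB:Z:%s", r$umi))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*\t%s",
                  r$read_id, ifelse(r$strand == "+", 0L, 16L), r$chrom,
                  r$pos, r$cigar, tags)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a complete toy study on disk
#'
#' Convenience wrapper: [simulate_annotation()] then [simulate_reads()] into
#' one directory.
#'
#' @param cfg An `sclnc_sim_config`.
#' @param dir Output directory.
#' @return List combining both results: `ann`, `relations`, `coding_gtf`,
#'   `lnc_gtf`, `sam`, `clusters`, `truth`.
#' @export
simulate_study <- function(cfg, dir) {
  sa <- simulate_annotation(cfg, dir)
  sr <- simulate_reads(cfg, sa, dir)
  c(sa, sr)
}

#' Simulate a pseudobulk count matrix with planted effects
#'
#' Direct NB simulation at the count-matrix level (no reads), for testing
#' the differential-expression machinery under known truth: two groups of
#' pseudobulk samples, a subset of genes carrying a planted log2 fold
#' change, per-sample depth factors, and NB noise at a common dispersion.
#'
#' @param n_genes Number of genes.
#' @param n_planted Number of genes with a planted effect (group B vs A).
#' @param lfc Magnitude of the planted log2 fold change.
#' @param direction `"up"` (default): all planted effects are +`lfc` in
#'   group B, which also exercises the compositional robustness of the
#'   normalisation; `"both"`: signs alternate, keeping the library
#'   composition balanced.
#' @param dispersion NB dispersion.
#' @param n_per_group Pseudobulk samples per group.
#' @param seed Integer seed.
#' @param base_mean_range Range of per-gene baseline means (log-uniform).
#' @param depth_range Per-sample depth multipliers (log-uniform).
#' @return List: `counts` (an `sclnc_counts` with a `group` column in the
#'   sample table) and `truth` (tibble: `gene_id`, `planted_lfc`).
#' @export
simulate_counts <- function(n_genes = 500, n_planted = 50, lfc = 2,
                            dispersion = 0.05, n_per_group = 10, seed = 1,
                            base_mean_range = c(20, 2000),
                            depth_range = c(0.7, 1.4),
                            direction = c("up", "both")) {
  direction <- match.arg(direction)
  set.seed(seed)
  n_s <- 2L * n_per_group
  mu <- exp(stats::runif(n_genes, log(base_mean_range[1]),
                         log(base_mean_range[2])))
  depth <- exp(stats::runif(n_s, log(depth_range[1]), log(depth_range[2])))
  planted <- rep(0, n_genes)
  if (n_planted > 0) {
    sgn <- if (direction == "both") {
      rep_len(c(1, -1), n_planted)
    } else rep(1, n_planted)
    planted[sample.int(n_genes, n_planted)] <- lfc * sgn
  }
  grp <- rep(c("A", "B"), each = n_per_group)
  m <- matrix(0L, n_genes, n_s)
  for (j in seq_len(n_s)) {
    mu_j <- mu * depth[j] * (if (grp[j] == "B") 2^planted else rep(1, n_genes))
    m[, j] <- stats::rnbinom(n_genes, mu = mu_j, size = 1 / dispersion)
  }
  gid <- sprintf("G%04d", seq_len(n_genes))
  sid <- sprintf("%s%02d", grp, rep(seq_len(n_per_group), 2))
  dimnames(m) <- list(gid, sid)
  cm <- count_matrix(m, tibble::tibble(sample_id = sid, group = grp))
  list(counts = cm,
       truth = tibble::tibble(gene_id = gid, planted_lfc = planted))
}
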