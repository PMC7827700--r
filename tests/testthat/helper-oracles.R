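# Independent brute-force oracles and tiny fixture builders. These are
# deliberately written as plain loops over tibbles, sharing no code with the
# package internals they check.

# quick annotation builder: genes as a tibble; exons default to one exon per
# gene covering the span
toy_ann <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "start", "end")]
  }
  gene_models(genes, exons)
}

# brute-force read assignment: loop over every (read, gene, block, exon)
# quadruple. Returns tibble(read = index, outcome, gene_id).
oracle_assign <- function(reads, genes, exons, strandness = "forward",
                          min_overlap = 1) {
  out <- character(nrow(reads))
  gid <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    blocks <- reads$blocks[[i]]
    same <- character(0)
    other <- character(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != reads$chrom[i]) next
      ex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
      hit <- FALSE
      for (b in seq_len(nrow(blocks))) {
        for (e in seq_len(nrow(ex))) {
          ov <- min(blocks[b, 2], ex$end[e]) - max(blocks[b, 1], ex$start[e]) + 1
          if (ov >= min_overlap) hit <- TRUE
        }
      }
      if (!hit) next
      strand_ok <- switch(strandness,
        forward = genes$strand[g] == reads$strand[i],
        reverse = genes$strand[g] != reads$strand[i],
        unstranded = TRUE
      )
      if (strand_ok) same <- c(same, genes$gene_id[g]) else
        other <- c(other, genes$gene_id[g])
    }
    if (length(same) == 1) {
      out[i] <- "assigned"
      gid[i] <- same
    } else if (length(same) >= 2) {
      out[i] <- "ambiguous"
    } else if (length(other) > 0 && strandness != "unstranded") {
      out[i] <- "strand_mismatch"
    } else {
      out[i] <- "no_feature"
    }
  }
  tibble::tibble(outcome = out, gene_id = gid)
}

# brute-force interval query over the gene/exon tables
oracle_query <- function(genes, exons, chrom, start, end, level) {
  hit <- character(0)
  for (g in seq_len(nrow(genes))) {
    if (genes$chrom[g] != chrom) next
    if (level == "span") {
      if (min(end, genes$end[g]) - max(start, genes$start[g]) >= 0) {
        hit <- c(hit, genes$gene_id[g])
      }
    } else {
      ex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
      for (e in seq_len(nrow(ex))) {
        if (min(end, ex$end[e]) - max(start, ex$start[e]) >= 0) {
          hit <- c(hit, genes$gene_id[g])
          break
        }
      }
    }
  }
  sort(unique(hit))
}

# brute-force BH from the definition: padj_i = min over thresholds t >= p_i
# of m * t / rank(t), evaluated at every observed p
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p, function(t) {
      if (t < pi) return(Inf)
      m * t / sum(p <= t)
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# brute-force nearest coding gap scan with the package-documented gap
# convention (overlap -> 0, disjoint -> later.start - earlier.end)
oracle_nearest <- function(lnc_row, coding) {
  cod <- coding[coding$chrom == lnc_row$chrom, , drop = FALSE]
  if (nrow(cod) == 0) return(list(coding_id = NA, gap = NA))
  gaps <- numeric(nrow(cod))
  for (g in seq_len(nrow(cod))) {
    if (min(lnc_row$end, cod$end[g]) >= max(lnc_row$start, cod$start[g])) {
      gaps[g] <- 0
    } else if (cod$start[g] > lnc_row$end) {
      gaps[g] <- cod$start[g] - lnc_row$end
    } else {
      gaps[g] <- lnc_row$start - cod$end[g]
    }
  }
  best <- which(gaps == min(gaps))
  best <- best[order(cod$gene_id[best])][1]
  list(coding_id = cod$gene_id[best], gap = gaps[best])
}

# random toy instance: genes (possibly overlapping, both strands, 1-2 exons)
# and reads (1-2 blocks) on one chromosome
random_instance <- function(n_genes, n_reads, chrom_len = 50000,
                            spliced = TRUE) {
  gs <- sort(sample.int(chrom_len - 2000, n_genes))
  glen <- sample(200:1500, n_genes, replace = TRUE)
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)), chrom = "chrT",
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = gs, end = gs + glen, biotype = "lncRNA"
  )
  exl <- list()
  for (g in seq_len(n_genes)) {
    if (genes$end[g] - genes$start[g] > 400 && stats::runif(1) < 0.5) {
      mid <- (genes$start[g] + genes$end[g]) %/% 2
      exl[[g]] <- tibble::tibble(
        gene_id = genes$gene_id[g],
        start = c(genes$start[g], mid + 60),
        end = c(mid - 60, genes$end[g])
      )
    } else {
      exl[[g]] <- tibble::tibble(gene_id = genes$gene_id[g],
                                 start = genes$start[g], end = genes$end[g])
    }
  }
  exons <- dplyr::bind_rows(exl)
  rs <- sample.int(chrom_len - 300, n_reads, replace = TRUE)
  blocks <- lapply(seq_len(n_reads), function(i) {
    if (spliced && stats::runif(1) < 0.3) {
      gap <- sample(50:500, 1)
      cbind(start = c(rs[i], rs[i] + 45 + gap),
            end = c(rs[i] + 44, rs[i] + 89 + gap))
    } else {
      cbind(start = rs[i], end = rs[i] + 89)
    }
  })
  reads <- tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n_reads)), chrom = "chrT",
    strand = sample(c("+", "-"), n_reads, replace = TRUE),
    start = rs, end = vapply(blocks, function(b) b[nrow(b), 2], numeric(1)),
    blocks = blocks, barcode = NA_character_, umi = NA_character_,
    nh = 1L, flag = 0L, mapq = 255L
  )
  list(genes = genes, exons = exons, ann = gene_models(genes, exons),
       reads = reads)
}

# minimal SAM writer for hand-built fixtures (independent of the simulator)
write_test_sam <- function(path, records, sq = c(chrT = 100000L)) {
  header <- c("@HD\tVN:1.6",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, cigar, mapq = 255,
                    tags = character(0)) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*", tags),
        collapse = "\t")
}
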