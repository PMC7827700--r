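ctx_ann <- function(lnc_start, lnc_end, coding = NULL, lnc_strand = "+") {
  if (is.null(coding)) {
    coding <- tibble::tibble(gene_id = "PC1", chrom = "chr1", strand = "+",
                             start = 10000L, end = 20000L,
                             biotype = "coding")
  }
  genes <- dplyr::bind_rows(
    coding,
    tibble::tibble(gene_id = "L1", chrom = "chr1", strand = lnc_strand,
                   start = as.integer(lnc_start), end = as.integer(lnc_end),
                   biotype = "lncRNA")
  )
  toy_ann(genes)
}

test_that("5 kb rule boundary: gaps 0/1/4999/5000 intragenic, 5001/6000 intergenic", {
  # lncRNA downstream of coding gene ending at 20000; gap = start - 20000
  for (gap in c(0, 1, 4999, 5000, 5001, 6000)) {
    start <- if (gap == 0) 19500L else 20000L + gap
    ctx <- classify_context(ctx_ann(start, start + 400L))
    expect_equal(ctx$gap_bp, gap)
    expect_equal(ctx$class, if (gap <= 5000) "intragenic" else "intergenic")
  }
})

test_that("relation and signed offset respect coding-gene orientation", {
  # overlap, opposite strand
  ctx <- classify_context(ctx_ann(15000, 16000, lnc_strand = "-"))
  expect_equal(ctx$relation, "overlapping_antisense")
  expect_equal(ctx$signed_offset, 0)
  # overlap, same strand
  expect_equal(classify_context(ctx_ann(15000, 16000))$relation,
               "overlapping_sense")
  # lncRNA after a + coding gene is downstream (positive offset)
  ctx_dn <- classify_context(ctx_ann(21000, 21500))
  expect_equal(ctx_dn$relation, "downstream")
  expect_equal(ctx_dn$signed_offset, ctx_dn$gap_bp)
  # same geometry with a - coding gene is upstream (negative offset)
  cod_minus <- tibble::tibble(gene_id = "PC1", chrom = "chr1", strand = "-",
                              start = 10000L, end = 20000L,
                              biotype = "coding")
  ctx_up <- classify_context(ctx_ann(21000, 21500, coding = cod_minus))
  expect_equal(ctx_up$relation, "upstream")
  expect_equal(ctx_up$signed_offset, -ctx_up$gap_bp)
})

test_that("nearest coding gene ties break lexicographically; empty chrom is intergenic", {
  coding <- tibble::tibble(
    gene_id = c("PCB", "PCA"), chrom = "chr1", strand = "+",
    start = c(1000L, 30000L), end = c(10000L, 40000L), biotype = "coding")
  # lncRNA equidistant from both (gap 5000 each side)
  ann <- ctx_ann(15000L, 25000L, coding = coding)
  ctx <- classify_context(ann)
  expect_equal(ctx$coding_id, "PCA")
  # lncRNA alone on its chromosome
  genes <- tibble::tibble(
    gene_id = c("PC1", "L1"), chrom = c("chr1", "chr2"),
    strand = "+", start = c(1000L, 1000L), end = c(2000L, 2000L),
    biotype = c("coding", "lncRNA"))
  ctx2 <- classify_context(toy_ann(genes))
  expect_equal(ctx2$class, "intergenic")
  expect_true(is.na(ctx2$coding_id))
})

test_that("classification matches the brute-force nearest-gap scan on random placements", {
  withr::local_seed(21)
  n_cod <- 40
  cs <- sort(sample.int(900000, n_cod))
  coding <- tibble::tibble(
    gene_id = sprintf("PC%03d", sample(n_cod)), chrom = "chr1",
    strand = sample(c("+", "-"), n_cod, replace = TRUE),
    start = cs, end = cs + sample(500:5000, n_cod, replace = TRUE),
    biotype = "coding")
  for (batch in 1:4) {
    n_lnc <- 50
    ls <- sample.int(950000, n_lnc)
    lnc <- tibble::tibble(
      gene_id = sprintf("L%03d", seq_len(n_lnc)), chrom = "chr1",
      strand = sample(c("+", "-"), n_lnc, replace = TRUE),
      start = ls, end = ls + sample(200:3000, n_lnc, replace = TRUE),
      biotype = "lncRNA")
    ann <- toy_ann(dplyr::bind_rows(coding, lnc))
    ctx <- classify_context(ann)
    for (i in seq_len(n_lnc)) {
      o <- oracle_nearest(lnc[i, ], coding)
      row <- ctx[ctx$lnc_id == lnc$gene_id[i], ]
      expect_equal(row$gap_bp, o$gap)
      expect_equal(row$class,
                   if (o$gap <= 5000) "intragenic" else "intergenic")
    }
  }
})

test_that("cis correlation: exact linear cases, nulls, degenerate input", {
  lin <- tibble::tibble(lnc_lfc = c(1, 2, 3), coding_lfc = c(2, 4, 6))
  expect_equal(cis_correlation(lin)$pearson_r, 1)
  neg <- tibble::tibble(lnc_lfc = c(1, 2, 3), coding_lfc = c(-1, -2, -3))
  expect_equal(cis_correlation(neg)$pearson_r, -1)
  expect_equal(neg |> cis_correlation() |> dplyr::pull(frac_concordant), 0)

  withr::local_seed(22)
  null <- tibble::tibble(lnc_lfc = rnorm(1000), coding_lfc = rnorm(1000))
  expect_lt(abs(cis_correlation(null)$pearson_r), 0.1)
  # order invariance and coordinate-swap symmetry
  perm <- null[sample(1000), ]
  expect_equal(cis_correlation(perm)$pearson_r,
               cis_correlation(null)$pearson_r)
  swapped <- dplyr::rename(null, lnc_lfc = coding_lfc, coding_lfc = lnc_lfc)
  expect_equal(cis_correlation(swapped)$pearson_r,
               cis_correlation(null)$pearson_r)
  # zero variance -> r undefined
  flat <- tibble::tibble(lnc_lfc = c(1, 1, 1), coding_lfc = c(1, 2, 3))
  expect_message(r <- cis_correlation(flat)$pearson_r, "zero variance")
  expect_true(is.na(r))
  expect_true(is.na(cis_correlation(lin[1:2, ])$pearson_r)) # < 3 pairs
})

test_that("cis_pairs joins shared-contrast fold changes and filters", {
  cfg <- sim_config(seed = 33, n_coding = 20, n_lnc = 15,
                    cells_per_cluster = 10, clusters_per_type = 2,
                    timepoints = c("day16", "day60"), frac_de_celltype = 0.4)
  dir <- withr::local_tempdir()
  sim <- simulate_study(cfg, dir)
  cm <- build_count_matrix(read_alignments(sim$sam), sim$ann,
                           read_cluster_map(sim$clusters))
  de <- run_de(cm, contrast = "cell_type")
  ctx <- classify_context(sim$ann)
  pr_all <- cis_pairs(ctx, de, significant = "none")
  expect_true(all(pr_all$gap_bp <= 5000))
  tested <- tidy(de)$gene_id
  expect_true(all(pr_all$lnc_id %in% tested))
  pr_both <- cis_pairs(ctx, de, significant = "both")
  expect_true(nrow(pr_both) <= nrow(pr_all))
  sig <- tidy(de)$gene_id[tidy(de)$significant]
  expect_true(all(pr_both$lnc_id %in% sig) && all(pr_both$coding_id %in% sig))
})

test_that("strand tally and length histogram are conserved partitions", {
  genes <- tibble::tibble(strand = c("+", "+", "+", "-", "-"),
                          mature_length = c(100, 400, 2600, 900, 12000))
  st <- strand_tally(genes)
  expect_equal(st$n_sense, 3)
  expect_equal(st$n_antisense, 2)
  expect_equal(st$n_sense + st$n_antisense, st$n_total)
  st0 <- strand_tally(genes[0, ])
  expect_equal(c(st0$n_sense, st0$n_antisense), c(0, 0))

  h <- length_distribution(c(100), breaks = c(0, 200, Inf))
  expect_equal(h$n, c(1L, 0L))
  withr::local_seed(23)
  lens <- sample(50:20000, 500, replace = TRUE)
  expect_equal(sum(length_distribution(lens)$n), 500)
})

test_that("distance matrix is Euclidean on log2 normalised counts", {
  withr::local_seed(24)
  m <- matrix(rpois(60, 50) + 1L, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[, 6] <- m[, 5] # duplicated sample
  d <- sample_distances(m, sf = rep(1, 6))
  expect_equal(d[5, 6], 0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  # one-gene difference of delta on the log2 scale
  m2 <- matrix(c(3L, 3L, 3L, 15L), 2, 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  d2 <- sample_distances(m2, sf = c(1, 1))
  expect_equal(d2[1, 2], abs(log2(16) - log2(4)))
  # brute-force pairwise oracle
  lg <- log2(sweep(m, 2, size_factors(m), "/") + 1)
  dd <- sample_distances(m)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(dd[i, j], sqrt(sum((lg[, i] - lg[, j])^2)))
  }
})

test_that("PCA separates planted groups, zeroes identical data, fixes signs", {
  sim <- simulate_counts(n_genes = 200, n_planted = 40, lfc = 3,
                         dispersion = 0.05, n_per_group = 6, seed = 25)
  pca <- pca_samples(sim$counts)
  co <- tidy(pca)
  a <- co$PC1[co$group == "A"]
  b <- co$PC1[co$group == "B"]
  # PC1 separates the groups with positive silhouette-like margin
  expect_true(max(min(a), min(b)) > min(max(a), max(b)) ||
                abs(mean(a) - mean(b)) >
                  2 * (stats::sd(a) + stats::sd(b)) / 2)
  expect_true(all(pca$var_explained >= 0 & pca$var_explained <= 1))
  expect_true(all(diff(pca$var_explained) <= 1e-10))
  # identical columns -> all coordinates 0
  mi <- matrix(rep(c(4L, 9L, 2L), 4), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pci <- suppressWarnings(pca_samples(mi, n_components = 2))
  expect_equal(max(abs(as.matrix(pci$coords[, -1]))), 0, tolerance = 1e-12)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(pca$rotation, 2,
                        function(r) r[which.max(abs(r))] > 0)))
})

test_that("MA table mirrors the DE result", {
  sim <- simulate_counts(n_genes = 80, n_planted = 8, n_per_group = 5,
                         seed = 26)
  de <- run_de(sim$counts, contrast = "group")
  ma <- ma_table(de)
  tab <- tidy(de)
  expect_equal(nrow(ma), nrow(tab))
  expect_equal(ma$log2_base_mean, log2(tab$baseMean))
  expect_equal(ma$significant, tab$significant)
  expect_setequal(ma$gene_id[ma$significant],
                  tab$gene_id[tab$significant])
})
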