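test_that("size factors: closed forms and scale equivariance", {
  m_id <- matrix(rep(c(5L, 9L, 14L), 4), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(size_factors(m_id)), rep(1, 4))

  m <- matrix(c(10, 30, 20, 60), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(0.7071, 1.4142), tolerance = 1e-4)

  withr::local_seed(8)
  m3 <- matrix(rpois(60, 40) + 1L, 10, 6)
  s0 <- size_factors(m3)
  m4 <- m3
  m4[, 3] <- m3[, 3] * 5L
  s1 <- size_factors(m4)
  # equivariance up to the common scale of the size-factor vector
  expect_equal(s1[3] / s1[-3], 5 * s0[3] / s0[-3])
})

test_that("size factors match the reference implementation and are row-order invariant", {
  skip_if_not_installed("DESeq2")
  withr::local_seed(9)
  m <- matrix(rnbinom(500, mu = 50, size = 5) + 1L, 50, 10)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
  expect_equal(unname(size_factors(m[sample(50), ])), unname(size_factors(m)))
})

test_that("size factors error when no reference gene exists", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_error(size_factors(m), "no gene has positive counts")
})

test_that("normalisation identities: raw counts, scaling, baseMean", {
  withr::local_seed(10)
  m <- matrix(rpois(40, 30) + 1L, 10, 4)
  expect_equal(normalized_counts(m, sf = rep(1, 4)), sclnc:::counts_of(m))
  n1 <- normalized_counts(m)
  m2 <- m
  m2[, 2] <- m[, 2] * 3L
  s <- size_factors(m)
  s2 <- s
  s2[2] <- s[2] * 3
  expect_equal(normalized_counts(m2, s2)[, 2], n1[, 2])
  expect_equal(base_means(m), rowMeans(normalized_counts(m)))
})

test_that("NB GLM coefficients and SEs match an independent GLM fit", {
  skip_if_not_installed("MASS")
  withr::local_seed(12)
  grp <- rep(c(0, 1), each = 8)
  X <- cbind(1, grp)
  sf <- exp(runif(16, -0.2, 0.2))
  alpha <- 0.08
  y <- rnbinom(16, mu = 60 * sf * 2^(1.2 * grp), size = 1 / alpha)
  ours <- sclnc:::fit_nb_glm(y, X, sf, alpha)
  ref <- glm(y ~ grp + offset(log(sf)),
             family = MASS::negative.binomial(theta = 1 / alpha))
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-5)
  # dispersion = 1: the NB variance is fully specified by alpha, with no
  # extra Pearson scale factor
  expect_equal(unname(ours$se),
               unname(summary(ref, dispersion = 1)$coefficients[, 2]),
               tolerance = 1e-4)
})

test_that("dispersion estimation: Poisson limit, NB recovery, zero variance", {
  withr::local_seed(13)
  # Poisson data -> estimates near the floor for most genes
  mp <- matrix(rpois(100 * 12, 80), 100, 12)
  X <- matrix(1, 12, 1)
  dp <- suppressWarnings(estimate_dispersions(mp, rep(1, 12), X))
  expect_gt(mean(dp < 0.01, na.rm = TRUE), 0.8)
  # NB alpha = 0.1, 20 samples per group, 500 genes
  sim <- simulate_counts(n_genes = 500, n_planted = 0, dispersion = 0.1,
                         n_per_group = 20, seed = 303,
                         depth_range = c(1, 1))
  m <- as.matrix(sim$counts)
  Xg <- design_matrix(sim$counts$samples$group)
  d <- suppressWarnings(estimate_dispersions(m, rep(1, 40), Xg))
  expect_gt(median(d, na.rm = TRUE), 0.05)
  expect_lt(median(d, na.rm = TRUE), 0.2)
  # constant gene
  mc <- matrix(7L, 1, 6)
  dc <- suppressWarnings(estimate_dispersions(mc, rep(1, 6),
                                              matrix(1, 6, 1)))
  expect_lt(dc[1], 1e-6)
})

test_that("Wald contrast: null symmetry, planted recovery, label antisymmetry", {
  withr::local_seed(14)
  # identical group means in a balanced design
  y <- rep(c(10L, 12L, 11L, 10L, 12L, 11L), 2)
  m <- matrix(y, 1, 12, dimnames = list("g1", paste0("s", 1:12)))
  X <- design_matrix(rep(c("A", "B"), each = 6))
  res <- nb_wald(m, rep(1, 12), c(g1 = 0.01), X)
  expect_lt(abs(res$log2FoldChange), 0.05)
  expect_gt(res$pvalue, 0.9)

  # planted |log2FC| = 2 with balanced signs (composition-neutral),
  # alpha = 0.05, 10 per group
  sim <- simulate_counts(n_genes = 300, n_planted = 30, lfc = 2,
                         dispersion = 0.05, n_per_group = 10, seed = 105,
                         direction = "both")
  de <- run_de(sim$counts, contrast = "group", alpha = 0.01)
  tab <- tidy(de)
  truth_lfc <- sim$truth$planted_lfc[match(tab$gene_id, sim$truth$gene_id)]
  planted <- truth_lfc != 0
  err <- tab$log2FoldChange[planted] - truth_lfc[planted]
  expect_gte(mean(abs(err) <= 0.3), 0.9)
  expect_lt(abs(mean(err)), 0.1)

  # swapping the two group labels negates every LFC, p-values unchanged
  tab2 <- tidy(run_de(sim$counts, contrast = "group", levels = c("B", "A")))
  expect_equal(tab2$log2FoldChange, -tab$log2FoldChange, tolerance = 1e-6)
  expect_equal(tab2$pvalue, tab$pvalue, tolerance = 1e-6)
})

test_that("BH adjustment: hand examples, oracle, and reference agreement", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(15)
  for (k in 1:20) {
    p <- round(runif(sample(1:10, 1)), 3)
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  # monotone in p rank; NA handling
  p <- c(0.001, NA, 0.4, 0.02)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(order(adj[!is.na(adj)]), order(p[!is.na(p)]))
})

test_that("run_de orchestration: filters, flags and degenerate settings", {
  sim <- simulate_counts(n_genes = 100, n_planted = 10, n_per_group = 5,
                         seed = 106)
  de <- run_de(sim$counts, contrast = "group", alpha = 0.01,
               min_base_mean = 1)
  tab <- tidy(de)
  expect_true(all(tab$padj >= tab$pvalue, na.rm = TRUE))
  expect_true(all(tab$padj[tab$significant] < 0.01))
  # padj < alpha set is a subset of p < alpha set
  expect_true(all(tab$pvalue[tab$significant] < 0.01))
  g <- glance(de)
  expect_equal(g$n_tested, nrow(tab))
  # infinite filter removes everything
  de_inf <- run_de(sim$counts, contrast = "group", min_base_mean = Inf)
  expect_equal(nrow(tidy(de_inf)), 0)
  # >2 levels needs explicit selection
  s3 <- sim$counts$samples
  s3$tp <- rep(c("day16", "day30", "day60"), length.out = nrow(s3))
  cm3 <- count_matrix(as.matrix(sim$counts), s3)
  expect_error(run_de(cm3, contrast = "tp"), "levels")
  de3 <- run_de(cm3, contrast = "tp", levels = c("day16", "day60"))
  expect_equal(de3$levels, c("day16", "day60"))
})

test_that("pipeline on its own model recovers planted effects without bias", {
  sim <- simulate_counts(n_genes = 400, n_planted = 40, lfc = 1.5,
                         dispersion = 0.05, n_per_group = 10, seed = 107)
  de <- run_de(sim$counts, contrast = "group")
  tab <- tidy(de)
  truth <- sim$truth[match(tab$gene_id, sim$truth$gene_id), ]
  err <- tab$log2FoldChange - truth$planted_lfc
  expect_lt(abs(mean(err)), 0.1)
})
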