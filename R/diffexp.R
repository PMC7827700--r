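#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: for each sample j,
#' `s_j = median_g( counts[g, j] / geomean_g )` over reference genes g,
#' where `geomean_g` is the geometric mean of gene g across all samples and
#' the reference set is the genes with strictly positive counts in every
#' sample. This corrects for sequencing depth and moderate composition
#' differences between pseudobulk samples.
#'
#' @param object An `sclnc_counts` object or a non-negative count matrix
#'   (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' size_factors(m)  # 0.7071 1.4142
#' @export
size_factors <- function(object) {
  m <- counts_of(object)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; size factors are ",
         "undefined (consider a pseudo-reference on a filtered matrix)",
         call. = FALSE)
  }
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  s <- apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("non-finite or non-positive size factor computed", call. = FALSE)
  }
  s
}

counts_of <- function(object) {
  if (inherits(object, "sclnc_counts")) return(object$counts)
  if (is.matrix(object)) {
    m <- object
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
    return(m)
  }
  stop("expected an sclnc_counts object or a count matrix", call. = FALSE)
}

#' Size-factor-normalised counts
#'
#' @param object `sclnc_counts` or count matrix.
#' @param sf Size factors; computed with [size_factors()] if missing.
#' @return Real matrix `counts[g, j] / sf[j]`.
#' @export
normalized_counts <- function(object, sf = NULL) {
  m <- counts_of(object)
  if (is.null(sf)) sf <- size_factors(m)
  stopifnot(length(sf) == ncol(m), all(sf > 0))
  sweep(m, 2, sf, "/")
}

#' log2(normalised + 1) transform
#'
#' The transform used for sample distances, PCA and expression heatmaps.
#'
#' @inheritParams normalized_counts
#' @return Real matrix of `log2(counts/sf + 1)`.
#' @export
log_normalized_counts <- function(object, sf = NULL) {
  log2(normalized_counts(object, sf) + 1)
}

#' Per-gene mean of normalised counts
#'
#' @inheritParams normalized_counts
#' @return Named numeric vector, the `baseMean` of each gene.
#' @export
base_means <- function(object, sf = NULL) {
  rowMeans(normalized_counts(object, sf))
}

# ---- NB GLM machinery ------------------------------------------------------

# IRLS fit of a negative-binomial GLM with log link, fixed dispersion alpha
# and offset log(sf). Returns beta, standard errors from observed Fisher
# information, fitted mu, and a convergence flag.
fit_nb_glm <- function(y, X, sf, alpha, maxit = 100L, tol = 1e-8) {
  offset <- log(sf)
  eta <- log(pmax(y, 0.5)) # working response start
  beta <- qr.solve(X, eta - offset)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  mu <- pmin(exp(drop(X %*% beta) + offset), 1e12)
  w <- mu / (1 + alpha * mu)
  info <- crossprod(X * sqrt(w))
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(X)))
  list(beta = beta, se = se, mu = mu, converged = converged)
}

nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood for the dispersion: the plain
# profile likelihood is biased low because the mean coefficients are
# estimated; subtracting half the log-determinant of the weighted design
# information removes the leading-order bias.
nb_cr_apl <- function(y, mu, alpha, X) {
  w <- mu / (1 + alpha * mu)
  ld <- determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
  nb_loglik(y, mu, alpha) - 0.5 * as.numeric(ld)
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Gene-wise maximum-likelihood dispersion under the design-fitted means:
#' starting from a method-of-moments value, the fit alternates between
#' refitting the NB GLM means at the current dispersion and maximising the
#' NB log-likelihood over dispersion (1-D optimisation on the log scale)
#' until the dispersion changes by less than `1e-6` or 20 rounds. Estimates
#' are floored at `1e-8`. If the likelihood maximisation fails, the
#' method-of-moments value is used with a warning. No shrinkage across genes
#' is applied.
#'
#' @param object `sclnc_counts` or count matrix.
#' @param sf Size factors (computed if `NULL`).
#' @param design Design matrix (samples x coefficients), e.g. from
#'   [design_matrix()]; defaults to intercept-only.
#' @param floor Minimum dispersion (default `1e-8`).
#' @return Numeric vector of dispersions, one per gene (NA for all-zero
#'   genes), with a `"method"` attribute (`"ML"` or `"MoM"` per gene).
#' @export
estimate_dispersions <- function(object, sf = NULL, design = NULL,
                                 floor = 1e-8) {
  m <- counts_of(object)
  if (is.null(sf)) sf <- size_factors(m)
  if (is.null(design)) design <- matrix(1, ncol(m), 1)
  stopifnot(nrow(design) == ncol(m), ncol(m) >= 2)
  n_genes <- nrow(m)
  alpha <- rep(NA_real_, n_genes)
  method <- rep(NA_character_, n_genes)
  n_fail <- 0L
  for (g in seq_len(n_genes)) {
    y <- m[g, ]
    if (all(y == 0)) next
    a <- dispersion_one_gene(y, design, sf, floor)
    alpha[g] <- a$alpha
    method[g] <- a$method
    n_fail <- n_fail + as.integer(a$method == "MoM")
  }
  if (n_fail > 0) {
    warning(n_fail, " gene(s) fell back to method-of-moments dispersion",
            call. = FALSE)
  }
  names(alpha) <- rownames(m)
  attr(alpha, "method") <- method
  alpha
}

dispersion_mom <- function(y, mu, floor) {
  # Pearson-style moment estimator pooled over residuals around fitted means
  num <- sum((y - mu)^2 - mu)
  den <- sum(mu^2)
  max(floor, num / den)
}

dispersion_one_gene <- function(y, X, sf, floor, max_rounds = 20L,
                                tol = 1e-6) {
  fit0 <- fit_nb_glm(y, X, sf, alpha = 0.1)
  mu <- fit0$mu
  alpha <- dispersion_mom(y, mu, floor)
  mom <- alpha
  ok <- TRUE
  for (r in seq_len(max_rounds)) {
    opt <- tryCatch(
      stats::optimize(function(la) -nb_cr_apl(y, mu, exp(la), X),
                      lower = log(floor), upper = log(100)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$objective)) {
      ok <- FALSE
      break
    }
    alpha_new <- max(floor, exp(opt$minimum))
    fit <- fit_nb_glm(y, X, sf, alpha_new)
    mu <- fit$mu
    if (abs(alpha_new - alpha) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  if (!ok) return(list(alpha = mom, method = "MoM"))
  list(alpha = alpha, method = "ML")
}

#' Build a two-level design matrix
#'
#' Intercept plus an indicator for the second level of `condition`
#' (reference level first), plus optional additive covariate indicators.
#'
#' @param condition Factor or character vector with exactly two levels; the
#'   first level (alphabetical unless already a factor) is the reference.
#' @param covariate Optional factor for an additive nuisance term.
#' @return Design matrix with attribute `"contrast_name"` naming the tested
#'   coefficient (`condition<level2>`).
#' @export
design_matrix <- function(condition, covariate = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) {
    stop("the active contrast must have exactly 2 levels, got ",
         nlevels(condition), call. = FALSE)
  }
  if (min(table(condition)) < 2) {
    warning("a contrast level has fewer than 2 pseudobulk replicates; ",
            "dispersion estimates will be unstable", call. = FALSE)
  }
  X <- stats::model.matrix(~condition)
  cname <- colnames(X)[2]
  if (!is.null(covariate)) {
    covariate <- as.factor(covariate)
    if (nlevels(covariate) > 1) {
      X <- stats::model.matrix(~condition + covariate)
    }
  }
  attr(X, "contrast_name") <- cname
  X
}

#' Negative-binomial Wald test for a two-level contrast
#'
#' Per gene, fits an NB GLM with log link, mean
#' `mu[g, j] = sf[j] * exp(X beta)` at the supplied gene-wise dispersion,
#' and tests the contrast coefficient with a Wald statistic.
#' `log2FoldChange` is the contrast coefficient divided by `ln 2`; its
#' standard error comes from the observed Fisher information. The reference
#' distribution is Student's t with residual degrees of freedom
#' (samples minus fitted coefficients), a small-sample calibration that
#' keeps the far tail honest with gene-wise dispersions; with many samples
#' it is indistinguishable from the normal reference. No fold-change
#' shrinkage is applied.
#'
#' @param object `sclnc_counts` or count matrix.
#' @param sf Size factors.
#' @param dispersions Per-gene dispersions from [estimate_dispersions()].
#' @param design Design matrix from [design_matrix()].
#' @return Tibble: `gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`, `stat`,
#'   `pvalue`, `converged`. Genes with all-zero counts carry NA test fields.
#' @export
nb_wald <- function(object, sf, dispersions, design) {
  m <- counts_of(object)
  stopifnot(length(sf) == ncol(m), length(dispersions) == nrow(m))
  cname <- attr(design, "contrast_name")
  ci <- if (!is.null(cname)) match(cname, colnames(design)) else 2L
  bm <- base_means(m, sf)
  n_genes <- nrow(m)
  lfc <- se <- rep(NA_real_, n_genes)
  conv <- rep(NA, n_genes)
  for (g in seq_len(n_genes)) {
    y <- m[g, ]
    if (all(y == 0) || is.na(dispersions[g])) next
    fit <- fit_nb_glm(y, design, sf, dispersions[g])
    lfc[g] <- fit$beta[ci] / log(2)
    se[g] <- fit$se[ci] / log(2)
    conv[g] <- fit$converged
  }
  stat <- lfc / se
  df_resid <- nrow(design) - ncol(design)
  pvalue <- if (df_resid > 0) 2 * stats::pt(-abs(stat), df = df_resid) else
    2 * stats::pnorm(-abs(stat))
  pvalue[!is.na(conv) & !conv] <- NA_real_
  tibble::tibble(
    gene_id = rownames(m), baseMean = unname(bm), log2FoldChange = lfc,
    lfcSE = se, stat = stat, pvalue = pvalue, converged = conv
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `padj_(i) = min_{k >= i} (m / k) * p_(k)`, capped at 1 and mapped back to
#' the input order; NA p-values are excluded from `m` and stay NA.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    out[ok] <- adj
  }
  out
}

#' Run the differential-expression pipeline for one contrast
#'
#' Orchestrates the negative-binomial Wald analysis: median-of-ratios size
#' factors on the full matrix, a baseMean expression filter, gene-wise ML
#' dispersion, per-gene NB GLM Wald test of the two-level contrast, and
#' Benjamini-Hochberg adjustment. Genes with `baseMean < min_base_mean` are
#' excluded before testing.
#'
#' @param object An `sclnc_counts` object (or count matrix together with
#'   `metadata`).
#' @param contrast Name of the sample-metadata column holding the two-level
#'   condition, e.g. `"cell_type"` or `"timepoint"`.
#' @param metadata Sample tibble with `sample_id` and the contrast column;
#'   defaults to the object's sample table. Samples outside the two contrast
#'   `levels` are dropped.
#' @param levels Optional length-2 character vector selecting and ordering
#'   the contrast levels (reference first); required when the column has
#'   more than two levels (e.g. `c("day16", "day60")` out of three days).
#' @param covariate Optional name of an additive covariate column.
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @param min_base_mean Expression filter on baseMean (default 1,
#'   inclusive).
#' @return An object of class `sclnc_de`; use [tidy()] for the per-gene
#'   table (`gene_id`, `baseMean`, `log2FoldChange`, `lfcSE`, `stat`,
#'   `pvalue`, `padj`, `significant`) and [glance()] for the one-row
#'   summary.
#' @export
run_de <- function(object, contrast, metadata = NULL, levels = NULL,
                   covariate = NULL, alpha = 0.01, min_base_mean = 1) {
  m <- counts_of(object)
  if (is.null(metadata)) {
    if (!inherits(object, "sclnc_counts")) {
      stop("metadata is required when object is a plain matrix", call. = FALSE)
    }
    metadata <- object$samples
  }
  metadata <- tibble::as_tibble(metadata)
  stopifnot("sample_id" %in% names(metadata),
            contrast %in% names(metadata))
  metadata <- metadata[match(colnames(m), metadata$sample_id), , drop = FALSE]
  cond <- as.character(metadata[[contrast]])
  if (is.null(levels)) levels <- sort(unique(cond))
  if (length(levels) != 2) {
    stop("contrast '", contrast, "' has ", length(levels),
         " levels; pass `levels = c(ref, alt)` to select two", call. = FALSE)
  }
  keep_s <- cond %in% levels
  m <- m[, keep_s, drop = FALSE]
  metadata <- metadata[keep_s, , drop = FALSE]
  cond <- factor(cond[keep_s], levels = levels)

  sf <- size_factors(m)
  bm <- base_means(m, sf)
  tested <- bm >= min_base_mean
  mt <- m[tested, , drop = FALSE]

  cov <- if (!is.null(covariate)) metadata[[covariate]] else NULL
  X <- design_matrix(cond, cov)
  if (nrow(mt) == 0) {
    res <- tibble::tibble(
      gene_id = character(0), baseMean = numeric(0),
      log2FoldChange = numeric(0), lfcSE = numeric(0), stat = numeric(0),
      pvalue = numeric(0), converged = logical(0)
    )
    disp <- numeric(0)
  } else {
    disp <- estimate_dispersions(mt, sf, X)
    res <- nb_wald(mt, sf, disp, X)
  }
  res$padj <- bh_adjust(res$pvalue)
  res$significant <- !is.na(res$padj) & res$padj < alpha
  res$dispersion <- as.numeric(unname(disp))

  structure(
    list(results = res, contrast = contrast, levels = levels,
         alpha = alpha, min_base_mean = min_base_mean,
         size_factors = sf, n_genes_input = length(bm),
         samples = metadata),
    class = "sclnc_de"
  )
}

#' @export
print.sclnc_de <- function(x, ...) {
  cat("<sclnc_de> contrast ", x$contrast, ": ", x$levels[2], " vs ",
      x$levels[1], " (reference)\n", sep = "")
  cat("  ", nrow(x$results), " genes tested (baseMean >= ", x$min_base_mean,
      " of ", x$n_genes_input, "); ", sum(x$results$significant),
      " significant at padj < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Tidy a differential-expression result
#'
#' @param x An `sclnc_de` object.
#' @param ... Unused.
#' @return Per-gene tibble with stable column names (`gene_id`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `padj`, `significant`).
#' @method tidy sclnc_de
#' @export
tidy.sclnc_de <- function(x, ...) {
  dplyr::select(x$results, "gene_id", "baseMean", "log2FoldChange",
                "lfcSE", "stat", "pvalue", "padj", "significant")
}

#' One-row summary of a differential-expression result
#'
#' @param x An `sclnc_de` object.
#' @param ... Unused.
#' @return Tibble with contrast, level, gene and significance counts.
#' @method glance sclnc_de
#' @export
glance.sclnc_de <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, reference = x$levels[1], alternative = x$levels[2],
    n_genes = x$n_genes_input, n_tested = nrow(x$results),
    n_significant = sum(x$results$significant), alpha = x$alpha,
    min_base_mean = x$min_base_mean
  )
}
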