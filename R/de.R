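# Differential expression: quantile normalization, location-scale batch
# adjustment, probe-to-gene collapse, empirical-Bayes moderated t with
# Bonferroni control, and up-regulated gene selection.

#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every sample column onto the same distribution: the value at rank r
#' in each column becomes the mean of the rank-r values across columns. Ties
#' within a column receive the average of the corresponding reference values
#' (linear interpolation at fractional average ranks).
#'
#' @param mat numeric matrix, features x samples (log2 scale).
#' @return matrix of the same shape with identical sorted column vectors.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  n <- nrow(mat)
  ref <- rowMeans(matrix(apply(mat, 2L, sort), nrow = n))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    out[, j] <- if (n == 1L) ref else approx(seq_len(n), ref, xout = r)$y
  }
  out
}

#' Location-scale batch adjustment
#'
#' Per gene, each batch's sub-vector is centered at the gene's pooled mean and
#' rescaled to the gene's pooled standard deviation (the square root of the
#' degrees-of-freedom-weighted mean of the within-batch variances). Genes with
#' zero variance inside a batch are passed through centered only. A simpler,
#' deterministic alternative to empirical-Bayes batch correction: adequate for
#' additive per-gene batch shifts.
#'
#' A batch entirely confounded with one condition group triggers a warning
#' (the adjustment is still performed).
#'
#' @param mat numeric matrix, features x samples.
#' @param batch batch label per sample.
#' @param group optional condition label per sample, used only for the
#'   confounding check.
#' @return adjusted matrix of the same shape.
#' @export
adjust_batches <- function(mat, batch, group = NULL) {
  mat <- as.matrix(mat)
  batch <- as.character(batch)
  stopifnot(length(batch) == ncol(mat), !anyNA(batch))
  tb <- table(batch)
  if (any(tb < 2L)) stop("every batch needs >= 2 samples")
  if (!is.null(group)) {
    confounded <- vapply(split(as.character(group), batch),
                         function(g) length(unique(g)) == 1L, logical(1))
    if (length(tb) > 1L && any(confounded))
      warning("batch(es) ", paste(names(tb)[confounded], collapse = ", "),
              " contain a single condition group; batch and condition are ",
              "confounded there")
  }
  if (length(tb) == 1L) return(mat)

  out <- mat
  idx <- split(seq_len(ncol(mat)), batch)
  gm <- rowMeans(mat)
  bm <- matrix(vapply(idx, function(j) rowMeans(mat[, j, drop = FALSE]),
                      numeric(nrow(mat))), nrow = nrow(mat))
  bv <- matrix(vapply(idx, function(j) apply(mat[, j, drop = FALSE], 1L, var),
                      numeric(nrow(mat))), nrow = nrow(mat))
  dfb <- vapply(idx, length, integer(1)) - 1L
  pooled_sd <- sqrt(as.vector(bv %*% dfb) / sum(dfb))
  for (b in seq_along(idx)) {
    j <- idx[[b]]
    centered <- mat[, j, drop = FALSE] - bm[, b]
    scale <- ifelse(bv[, b] > 0, pooled_sd / sqrt(bv[, b]), 1)
    out[, j] <- centered * scale + gm
  }
  out
}

#' Collapse probe-level rows to gene-level rows
#'
#' One output row per gene: the per-sample summary (mean by default) over all
#' probes mapped to that gene. Probes absent from the map are dropped with a
#' message reporting the count.
#'
#' @param mat numeric matrix, probes x samples, rownames = probe ids.
#' @param probe_map data.frame with columns `probe` and `gene`.
#' @param fun summary: `"mean"` (default), `"median"` or `"max"`.
#' @return numeric matrix, genes x samples, rows sorted by gene id.
#' @export
collapse_probes <- function(mat, probe_map, fun = c("mean", "median", "max")) {
  fun <- match.arg(fun)
  mat <- as.matrix(mat)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  keep <- rownames(mat) %in% probe_map$probe
  if (!any(keep)) stop("no matrix feature is present in the probe map")
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " unmapped probe(s) dropped")
  mat <- mat[keep, , drop = FALSE]
  gene <- probe_map$gene[match(rownames(mat), probe_map$probe)]
  f <- switch(fun, mean = mean, median = stats::median, max = max)
  groups <- split(seq_len(nrow(mat)), gene)
  out <- t(vapply(groups,
                  function(i) apply(mat[i, , drop = FALSE], 2L, f),
                  numeric(ncol(mat))))
  out <- out[order(rownames(out)), , drop = FALSE]
  colnames(out) <- colnames(mat)
  out
}

# Newton inversion of the trigamma function (psi'(x) = y, y > 0)
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Moment-matching estimate of the variance prior (d0, s0^2) from gene-wise
# sample variances s2 on d degrees of freedom, via the marginal distribution
# of log s2: var(log s2) = trigamma(d/2) + trigamma(d0/2), E log s2 =
# log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2).
estimate_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  if (length(z) < 2L)
    stop("too few genes with positive variance to estimate the prior")
  vz <- var(z)
  ez <- mean(z)
  if (vz < 1e-10) {
    # no observed dispersion (to numerical precision): the sampling model is
    # contradicted; pass the common variance through unshrunk
    return(list(d0 = Inf, s02 = exp(ez)))
  }
  excess <- vz - trigamma(d / 2)
  if (excess <= 0) {
    # all spread is explained by chi-square sampling noise
    return(list(d0 = Inf, s02 = exp(ez - digamma(d / 2) + log(d / 2))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s02 <- exp(ez - digamma(d / 2) + log(d / 2) +
               digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t test
#'
#' For each gene the pooled residual variance s2_g on d = n1 + n2 - 2 degrees
#' of freedom is shrunk toward a prior s0^2 estimated from all genes:
#' `s_tilde2 = (d0 * s0^2 + d * s2_g) / (d0 + d)`. The moderated statistic is
#' `t = log2FC / (s_tilde * sqrt(1/n1 + 1/n2))`, referred to a t distribution
#' on d0 + d degrees of freedom (two-sided p). The prior (d0, s0^2) is
#' obtained by closed-form moment matching on log s2 (digamma/trigamma
#' inversion); when the observed spread of log s2 does not exceed its
#' chi-square sampling component the prior degrees of freedom are infinite
#' and every gene is assigned the common variance. Bonferroni-adjusted
#' p-values use m = number of tested genes.
#'
#' @param mat numeric gene x sample matrix (log2 scale).
#' @param group condition label per sample; see `case`/`control`.
#' @param case,control the labels of the two groups; log2FC = mean(case) −
#'   mean(control).
#' @param fc_threshold,alpha selection thresholds recorded in the `selected`
#'   column (see [select_upregulated()]).
#' @return data.frame of class `de_result`: gene, log2fc, s2, s2_post, t,
#'   df_total, p, p_bonf, selected; the prior is stored in attributes `d0`
#'   and `s02`.
#' @export
moderated_t <- function(mat, group, case = "case", control = "control",
                        fc_threshold = 2, alpha = 0.05) {
  mat <- as.matrix(mat)
  group <- as.character(group)
  stopifnot(length(group) == ncol(mat), !anyNA(group))
  i1 <- which(group == control)
  i2 <- which(group == case)
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need >= 2 samples per group")
  n1 <- length(i1); n2 <- length(i2)
  d <- n1 + n2 - 2L

  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  log2fc <- m2 - m1
  ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, i2, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  if (all(s2 == 0))
    stop("zero residual variance in every gene; nothing to moderate")

  prior <- estimate_variance_prior(s2, d)
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- log2fc / se
  df_total <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  m <- length(p)
  res <- data.frame(gene = rownames(mat) %||% as.character(seq_len(m)),
                    log2fc = log2fc, s2 = s2, s2_post = s2_post, t = tstat,
                    df_total = df_total, p = p,
                    p_bonf = pmin(1, m * p), row.names = NULL,
                    stringsAsFactors = FALSE)
  res$selected <- res$log2fc >= log2(fc_threshold) & res$p_bonf < alpha
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "n_per_group") <- c(control = n1, case = n2)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Select significantly up-regulated genes
#'
#' Genes with log2 fold change at or above `log2(fc_threshold)` (the "at
#' least"-fold boundary is inclusive) and Bonferroni-adjusted p below `alpha`,
#' sorted by descending log2 fold change.
#'
#' @param results a [moderated_t()] result.
#' @param fc_threshold fold-change threshold on the natural scale (default 2).
#' @param alpha significance level applied to the Bonferroni-adjusted p.
#' @return character vector of gene ids (possibly empty).
#' @export
select_upregulated <- function(results, fc_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(results, "de_result"), fc_threshold > 0)
  sel <- results$log2fc >= log2(fc_threshold) & results$p_bonf < alpha
  res <- results[sel, , drop = FALSE]
  res$gene[order(-res$log2fc)]
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Moderated-t results for %d genes (d0 = %.3g, s0^2 = %.4g)\n",
              nrow(x), attr(x, "d0"), attr(x, "s02")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
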