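# Differential expression: normalization, batch adjustment, probe collapse,
# moderated t and selection.

test_that("quantile normalization maps columns onto the rank-wise means", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # idempotent on identical columns
  eq <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(eq), eq)

  # single row: every entry becomes the row mean
  one <- matrix(c(2, 8), nrow = 1)
  expect_equal(unname(quantile_normalize(one)), matrix(5, 1, 2))

  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), ">= 2 samples")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(11)
  m <- matrix(rnorm(500), nrow = 100, ncol = 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("batch adjustment recenters and rescales each batch", {
  # single batch: identity
  m <- matrix(rnorm(40), nrow = 4)
  expect_equal(adjust_batches(m, rep("b1", 10)), m)

  # 1-gene toy: batch means 0 and 4, equal sizes and variances -> both
  # batches end at the pooled mean 2
  g <- matrix(c(-1, 1, 3, 5), nrow = 1)     # batch1: -1,1 ; batch2: 3,5
  adj <- adjust_batches(g, c("b1", "b1", "b2", "b2"))
  expect_equal(mean(adj[1, 1:2]), 2)
  expect_equal(mean(adj[1, 3:4]), 2)
  expect_equal(sd(adj[1, 1:2]), sd(adj[1, 3:4]))

  # constant gene: passes through centered (i.e. unchanged values)
  const <- matrix(5, nrow = 1, ncol = 6)
  expect_equal(adjust_batches(const, rep(c("b1", "b2"), each = 3)), const)

  # confounded batch triggers a warning but still adjusts
  mm <- matrix(rnorm(24), nrow = 2)
  expect_warning(
    adjust_batches(mm, rep(c("b1", "b2"), each = 6),
                   group = rep(c("case", "control"), each = 6)),
    "confounded")

  expect_error(adjust_batches(m, c("b1", rep("b2", 9))), ">= 2 samples")
})

test_that("batch adjustment removes planted additive shifts", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 200, n_samples_per_group = 8, n_batches = 2,
    batch_shift_sd = 2, de_fraction = 0, seed = 5))
  adj <- adjust_batches(sim$values, sim$samples$batch, sim$samples$group)
  # per-gene batch-mean differences collapse to ~0 after adjustment
  b <- sim$samples$batch
  gap_before <- rowMeans(sim$values[, b == 1]) - rowMeans(sim$values[, b == 2])
  gap_after <- rowMeans(adj[, b == 1]) - rowMeans(adj[, b == 2])
  expect_gt(sd(gap_before), 10 * sd(gap_after))
})

test_that("probe collapse averages probes per gene", {
  m <- rbind(p1 = c(1, 3), p2 = c(3, 5))
  map <- data.frame(probe = c("p1", "p2"), gene = c("G1", "G1"))
  expect_equal(unname(collapse_probes(m, map)["G1", ]), c(2, 4))

  # one probe per gene: unchanged values
  map2 <- data.frame(probe = c("p1", "p2"), gene = c("G1", "G2"))
  out <- collapse_probes(m, map2)
  expect_equal(unname(out["G1", ]), c(1, 3))
  expect_equal(unname(out["G2", ]), c(3, 5))

  # random map equals an independent group-by mean
  set.seed(21)
  mm <- matrix(rnorm(60), nrow = 12,
               dimnames = list(sprintf("p%02d", 1:12), NULL))
  map3 <- data.frame(probe = rownames(mm),
                     gene = sample(sprintf("G%d", 1:5), 12, replace = TRUE))
  got <- collapse_probes(mm, map3)
  want <- apply(mm, 2, function(col) tapply(col, map3$gene, mean))
  expect_equal(got, want[rownames(got), ])

  # unmapped probes dropped with a message; empty intersection errors
  expect_message(collapse_probes(mm, map3[1:10, ]), "dropped")
  expect_error(collapse_probes(mm, data.frame(probe = "zz", gene = "G")),
               "no matrix feature")
})

test_that("moderated t handles degenerate and limiting cases", {
  grp <- rep(c("control", "case"), each = 4)

  # identical group means: t = 0, p = 1
  x <- rbind(flat = c(1, 2, 3, 4, 1, 2, 3, 4),
             de = c(0, 0, 0, 0, 5, 5, 6, 6))
  res <- moderated_t(x, grp)
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_gt(res$t[2], 0)

  # equal residual variance in every gene: moderated t equals the ordinary
  # two-sample t exactly (pass-through branch)
  resid <- c(-1, 1, -1, 1, -2, 2, 0, 0)
  y <- rbind(g1 = resid + rep(c(0, 1), each = 4),
             g2 = resid + rep(c(0, 3), each = 4),
             g3 = resid + rep(c(2, 2), each = 4))
  resy <- moderated_t(y, grp)
  expect_true(is.infinite(attr(resy, "d0")))
  expect_equal(resy$s2_post, resy$s2)
  tt <- apply(y, 1, function(v) t.test(v[5:8], v[1:4],
                                       var.equal = TRUE)$statistic)
  expect_equal(resy$t, unname(tt), tolerance = 1e-10)

  # all-zero variance is an explicit error
  z <- rbind(a = rep(c(0, 1), each = 4), b = rep(c(2, 5), each = 4))
  expect_error(moderated_t(z, grp), "zero residual variance")

  expect_error(moderated_t(x[, 1:5], grp[1:5]), ">= 2 samples")
})

test_that("moderated t shrinks variances within the documented bounds", {
  sim <- simulate_expression(expression_sim_config(n_genes = 400, seed = 8))
  res <- moderated_t(sim$values, sim$samples$group)
  s02 <- attr(res, "s02")
  expect_true(all(res$s2_post >= pmin(res$s2, s02) - 1e-12))
  expect_true(all(res$s2_post <= pmax(res$s2, s02) + 1e-12))
  expect_true(all(res$p_bonf >= res$p))
  expect_true(all(res$p_bonf <= 1))
})

test_that("variance prior recovery on synthetic data", {
  # constant true noise: s0^2 should recover noise_sd^2 within 20%
  cfg <- expression_sim_config(n_genes = 2000, de_fraction = 0,
                               n_batches = 1, seed = 13)
  sim <- simulate_expression(cfg)
  res <- moderated_t(sim$values, sim$samples$group)
  expect_lt(abs(attr(res, "s02") - cfg$noise_sd^2), 0.2 * cfg$noise_sd^2)
})

test_that("moderated t agrees with the limma cross-check", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(expression_sim_config(n_genes = 500, seed = 17))
  res <- moderated_t(sim$values, sim$samples$group)
  design <- cbind(1, sim$samples$group == "case")
  fit <- limma::eBayes(limma::lmFit(sim$values, design))
  expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(res$s2, unname(fit$sigma^2), tolerance = 1e-10)
  # hyperparameters come from the same moment-matching family; allow modest
  # numerical differences between the two estimators
  expect_equal(attr(res, "s02"), fit$s2.prior, tolerance = 0.05)
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.2)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 0.02)
})

test_that("up-regulated selection applies inclusive fold-change and
           Bonferroni thresholds", {
  res <- structure(data.frame(
    gene = c("a", "b", "c", "d"),
    log2fc = c(1.0, 2.0, 3.0, 0.8),
    s2 = 1, s2_post = 1, t = 5, df_total = 10,
    p = c(1e-5, 0.05, 1e-6, 1e-6),
    p_bonf = c(0.01, 0.2, 4e-6, 4e-6),
    selected = NA, stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"))
  sel <- select_upregulated(res, fc_threshold = 2, alpha = 0.05)
  expect_identical(sel, c("c", "a"))    # boundary log2fc = 1 included,
                                        # high-p excluded, sorted by fc
  # monotonicity in both thresholds
  expect_lte(length(select_upregulated(res, fc_threshold = 4)),
             length(select_upregulated(res, fc_threshold = 2)))
  expect_lte(length(select_upregulated(res, alpha = 0.001)),
             length(select_upregulated(res, alpha = 0.05)))
  expect_identical(select_upregulated(res, fc_threshold = 64),
                   character(0))
})

test_that("the DE pipeline is deterministic for fixed input", {
  sim <- simulate_expression(expression_sim_config(n_genes = 150, seed = 23))
  r1 <- moderated_t(quantile_normalize(sim$values), sim$samples$group)
  r2 <- moderated_t(quantile_normalize(sim$values), sim$samples$group)
  expect_identical(r1, r2)
})
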