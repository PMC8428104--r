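test_that("TMM factors are unity for identical libraries and equalize pure depth shifts", {
  m <- make_nb_matrix(n_samples = 2, seed = 1)
  same <- cbind(a = m[, 1], b = m[, 1])
  norm <- tmm_normalize(same)
  expect_equal(unname(norm$factors), c(1, 1))

  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  n2 <- tmm_normalize(doubled)
  expect_equal(n2$cpm[, "a"], n2$cpm[, "b"], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(exp(mean(log(n2$factors))), 1, tolerance = 1e-12)
  expect_error(tmm_normalize(cbind(a = m[, 1], b = 0L * m[, 1])), "all-zero")
})

test_that("TMM factors agree with an independent reimplementation to 1e-10", {
  m <- make_nb_matrix(n_genes = 2000, n_samples = 6, seed = 17)
  # unequal depths and a block of distorted genes to make trimming bite
  m[, 3] <- m[, 3] * 3L
  m[1:100, 5] <- m[1:100, 5] * 8L
  norm <- tmm_normalize(m)
  oracle <- brute_force_tmm(m, ref = norm$ref_column)
  expect_equal(unname(norm$factors), unname(oracle), tolerance = 1e-10)
})

test_that("TMM factors match edgeR when forced onto the same reference", {
  skip_if_not_installed("edgeR")
  m <- make_nb_matrix(n_genes = 1500, n_samples = 6, seed = 23)
  m[, 2] <- m[, 2] * 2L
  norm <- tmm_normalize(m)
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = norm$ref_column)
  expect_equal(unname(norm$factors), unname(theirs), tolerance = 1e-10)
})

test_that("normalized CPM is nearly invariant to scaling one library", {
  # not exactly invariant: TMM's precision weights depend on depth, so a
  # 5x deeper library changes the weighting slightly
  m <- make_nb_matrix(n_genes = 800, n_samples = 4, seed = 5)
  n1 <- tmm_normalize(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 5L
  n2 <- tmm_normalize(m2)
  expect_equal(n1$cpm[, 2], n2$cpm[, 2], tolerance = 0.01)
})

test_that("duplicated condition groups yield zero significant genes", {
  samples <- make_triad_samples(2)
  m <- make_nb_matrix(n_genes = 400, n_samples = 6, seed = 2)
  # control and heat of each population are copies of the same columns
  counts <- matrix(0L, 400, nrow(samples),
                   dimnames = list(rownames(m), samples$sample))
  for (pop in c("P1", "P2", "F1")) {
    for (k in 1:2) {
      col <- m[, (match(pop, c("P1", "P2", "F1")) - 1) * 2 + k]
      counts[, sprintf("%s_C_%d", pop, k)] <- col
      counts[, sprintf("%s_H_%d", pop, k)] <- col
    }
  }
  norm <- tmm_normalize(counts)
  degs <- call_degs(norm, samples, "P1")
  expect_equal(sum(degs$significant), 0)
  expect_equal(degs$log2fc, rep(0, 400))
})

test_that("planted fold-changes are recovered with controlled FDR", {
  # additive background at solid coverage: planted dominance extremes
  # would push some genes to near-zero expression, and no three-replicate
  # test (count-model or otherwise) has power on a handful of reads
  cfg <- triad_sim_config(n_genes = 2000, dispersion = 0.01,
                          class_proportions = c(ADD = 1),
                          baseline_log_mean = 11, baseline_log_sd = 0.8,
                          de_fraction = 0.1, de_log2fc = 3, seed = 31)
  sim <- simulate_triad_counts(cfg)
  norm <- tmm_normalize(sim$counts)
  degs <- call_degs(norm, sim$samples, "F1")
  truth_de <- sim$truth$de[match(degs$gene, sim$truth$gene)]
  sens <- mean(degs$significant[truth_de])
  fdr_obs <- if (sum(degs$significant) > 0) {
    mean(!truth_de[degs$significant])
  } else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr_obs, 0.1)
  # direction matches the planted sign
  sig <- degs$significant & truth_de
  planted_sign <- sign(sim$truth$de_log2fc[match(degs$gene, sim$truth$gene)])
  expect_true(all(sign(degs$log2fc[sig]) == planted_sign[sig]))
})

test_that("swapping condition labels negates every log2 fold-change", {
  cfg <- triad_sim_config(n_genes = 300, de_fraction = 0.2, de_log2fc = 2, seed = 6)
  sim <- simulate_triad_counts(cfg)
  norm <- tmm_normalize(sim$counts)
  degs <- call_degs(norm, sim$samples, "P2")
  flipped <- sim$samples
  flipped$condition <- ifelse(flipped$condition == "control", "heat", "control")
  degs_f <- call_degs(norm, flipped, "P2")
  expect_equal(degs$log2fc, -degs_f$log2fc)
  expect_equal(degs$p, degs_f$p)
})

test_that("row-wise Welch matches stats::t.test and BH adjustment is monotone", {
  a <- withr::with_seed(41, matrix(rnorm(50 * 4, 5), 50))
  b <- withr::with_seed(42, matrix(rnorm(50 * 3, 5.5), 50))
  res <- heterosiskit:::row_welch(a, b)
  for (i in c(1, 17, 50)) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$diff[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  # BH as applied to DE output: adjusted >= raw, non-decreasing in raw order
  adj <- p.adjust(res$p, method = "BH")
  ord <- order(res$p)
  expect_true(all(adj >= res$p))
  expect_true(all(diff(adj[ord]) >= -1e-15))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
})

test_that("call_degs requires replicated conditions", {
  cfg <- triad_sim_config(n_genes = 100, n_replicates = 1, seed = 8)
  sim <- simulate_triad_counts(cfg)
  norm <- tmm_normalize(sim$counts)
  expect_error(call_degs(norm, sim$samples, "P1"), "2 replicates")
})
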