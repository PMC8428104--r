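test_that("d/|a| matches direct arithmetic and handles equal parents", {
  # hybrid at mid-parent
  expect_equal(compute_d_over_a(14, 10, 12), 0)
  # hybrid at the high parent under the full-gap denominator: (14-12)/4
  expect_equal(compute_d_over_a(14, 10, 14), 0.5)
  # half-gap convention doubles every full-gap ratio
  p1 <- c(14, 3, 8); p2 <- c(10, 9, 8.5); f1 <- c(14, 1, 9)
  expect_equal(compute_d_over_a(p1, p2, f1, convention = "half_gap"),
               2 * compute_d_over_a(p1, p2, f1))
  # equal parents: sentinel, not division
  expect_true(is.na(compute_d_over_a(10, 10, 15, epsilon = 1e-8)))
  expect_error(compute_d_over_a(NA_real_, 1, 2), "finite")
})

test_that("ratio is symmetric in the parents", {
  withr::with_seed(11, {
    p1 <- rnorm(50, 10); p2 <- rnorm(50, 8); f1 <- rnorm(50, 9)
  })
  r12 <- compute_d_over_a(p1, p2, f1)
  r21 <- compute_d_over_a(p2, p1, f1)
  expect_equal(abs(r12), abs(r21))
  lab12 <- classify_mode(r12); lab21 <- classify_mode(r21)
  expect_equal(lab12 %in% c("ADD"), lab21 %in% c("ADD"))
})

test_that("class boundaries follow the printed intervals exactly", {
  expect_equal(as.character(classify_mode(c(-0.2, 0.2))), c("ADD", "ADD"))
  expect_equal(as.character(classify_mode(1.2)), "HPD")
  expect_equal(as.character(classify_mode(1.2000001)), "ODO")
  expect_equal(as.character(classify_mode(-1.2)), "LPD")
  expect_equal(as.character(classify_mode(-1.2000001)), "UDO")
  expect_equal(as.character(classify_mode(c(-0.8, -0.2000001))), c("NPD", "NPD"))
  expect_equal(as.character(classify_mode(c(0.2000001, 0.8))), c("PPD", "PPD"))
  expect_error(classify_mode(NaN), "NA")
})

test_that("the seven intervals partition the line", {
  ratios <- withr::with_seed(5, c(runif(2e4, -4, 4),
                                  rnorm(5e3, 0, 2),
                                  c(-1.2, -0.8, -0.2, 0.2, 0.8, 1.2)))
  labels <- classify_mode(ratios)
  # every ratio got exactly one of the seven labels
  expect_false(anyNA(labels))
  expect_true(all(labels %in% c("UDO", "LPD", "NPD", "ADD", "PPD", "HPD", "ODO")))
})

test_that("classify_matrix recovers a noiseless planted triad exactly", {
  # replicate columns identical, so realized group means equal the
  # planted means; a ballast gene equalizes library sizes so the CPM
  # rescaling is a common constant and log2 ratios survive untouched
  samples <- make_triad_samples(2)
  ratios <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 0.3)
  base <- 10; gap <- 2
  p1 <- rep(2^(base + gap / 2), length(ratios))
  p2 <- rep(2^(base - gap / 2), length(ratios))
  f1 <- 2^(base + ratios * gap)
  counts <- matrix(0, nrow = length(ratios), ncol = nrow(samples),
                   dimnames = list(sprintf("g%d", seq_along(ratios)), samples$sample))
  for (j in seq_len(nrow(samples))) {
    counts[, j] <- round(switch(samples$population[j], P1 = p1, P2 = p2, F1 = f1))
  }
  ballast <- max(colSums(counts)) + 10000 - colSums(counts)
  counts <- rbind(counts, ballast = ballast)
  calls <- classify_matrix(counts, samples, condition = "control",
                           normalization = "log2")
  got <- calls[match(sprintf("g%d", seq_along(ratios)), calls$gene), ]
  expect_equal(got$ratio, ratios, tolerance = 1e-3)
  expect_equal(as.character(got$label), as.character(classify_mode(ratios)))
})

test_that("classification is invariant to sample order and drops undetected genes", {
  cfg <- triad_sim_config(n_genes = 300, seed = 4)
  sim <- simulate_triad_counts(cfg)
  counts <- sim$counts
  counts[5, sim$samples$sample[sim$samples$condition == "heat"]] <- 0L
  calls <- classify_matrix(counts, sim$samples, condition = "heat",
                           normalization = "log2")
  perm <- withr::with_seed(8, sample(ncol(counts)))
  calls2 <- classify_matrix(counts[, perm], sim$samples[match(colnames(counts)[perm], sim$samples$sample), ],
                            condition = "heat", normalization = "log2")
  expect_equal(calls, calls2, ignore_attr = TRUE)
  expect_true(rownames(counts)[5] %in% attr(calls, "undetected"))
  expect_false(rownames(counts)[5] %in% calls$gene)
})

test_that("classify_matrix names the missing population", {
  cfg <- triad_sim_config(n_genes = 50, seed = 2)
  sim <- simulate_triad_counts(cfg)
  keep <- sim$samples$population != "P2"
  expect_error(
    classify_matrix(sim$counts[, sim$samples$sample[keep]], sim$samples[keep, ],
                    condition = "control"),
    "P2"
  )
})

test_that("summarize_modes reproduces printed class shares from raw counts", {
  # heat-condition class counts of the published triad
  heat <- rep(c("ADD", "HPD", "LPD", "ODO", "UDO", "PPD", "NPD"),
              c(1457, 1119, 1278, 8235, 5819, 2047, 2014))
  s <- summarize_modes(heat)
  expect_equal(s$n_detected, 21969)
  expect_equal(s$n_non_additive, 20512)
  expect_equal(s$pct_non_additive, 93.37)
  expect_equal(unname(s$class_pct[c("ODO", "UDO", "HPD", "NPD", "PPD", "LPD")]),
               c(40.15, 28.37, 5.46, 9.82, 9.98, 6.23))
  # control-condition counts
  ctrl <- rep(c("ADD", "HPD", "LPD", "ODO", "UDO", "PPD", "NPD"),
              c(1763, 1354, 1559, 7061, 5590, 2280, 2362))
  sc <- summarize_modes(ctrl)
  expect_equal(sc$n_detected, 21969)
  expect_equal(sc$pct_non_additive, 91.98)
  expect_equal(unname(sc$class_pct[c("HPD", "UDO")]), c(6.70, 27.67))
})

test_that("summary counts round-trip the input labels", {
  labs <- withr::with_seed(3, sample(c("ADD", "PPD", "ODO", "UDO", "PARENT_EQUAL"),
                                     500, replace = TRUE))
  s <- summarize_modes(labs)
  expect_equal(sum(s$counts), 500)
  expect_equal(unname(s$counts[c("ADD", "PPD", "ODO", "UDO", "PARENT_EQUAL")]),
               unname(as.integer(table(factor(labs, levels = c("ADD", "PPD", "ODO", "UDO", "PARENT_EQUAL"))))))
  expect_equal(s$n_non_additive,
               sum(!labs %in% c("ADD", "PARENT_EQUAL")))
  all_add <- summarize_modes(rep("ADD", 10))
  expect_equal(all_add$pct_non_additive, 0)
  expect_error(summarize_modes(character(0)), "no mode calls")
})
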