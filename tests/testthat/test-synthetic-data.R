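test_that("triad generator is reproducible and validates its config", {
  cfg <- triad_sim_config(n_genes = 200, seed = 7)
  a <- simulate_triad_counts(cfg)
  b <- simulate_triad_counts(cfg)
  expect_identical(a, b)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_equal(nrow(a$samples), 18)
  expect_equal(sort(unique(a$samples$population)), c("F1", "P1", "P2"))

  expect_error(triad_sim_config(dispersion = 0), "dispersion")
  expect_error(triad_sim_config(class_proportions = c(ADD = 0.5, ODO = 0.4)),
               "sum to 1")
  expect_error(triad_sim_config(n_genes = 0), "n_genes")
  expect_error(triad_sim_config(library_size_factors = rep(-1, 18)), "positive")
})

test_that("planted targets lie inside their class intervals and truth is exact", {
  cfg <- triad_sim_config(n_genes = 1500, seed = 21)
  sim <- simulate_triad_counts(cfg)
  tr <- sim$truth
  intervals <- list(UDO = c(-Inf, -1.2), LPD = c(-1.2, -0.8), NPD = c(-0.8, -0.2),
                    ADD = c(-0.2, 0.2), PPD = c(0.2, 0.8), HPD = c(0.8, 1.2),
                    ODO = c(1.2, Inf))
  for (lab in names(intervals)) {
    t_lab <- tr$d_over_a_target[tr$class == lab]
    if (!length(t_lab)) next
    expect_true(all(t_lab > intervals[[lab]][1] & t_lab < intervals[[lab]][2]),
                label = sprintf("targets of %s inside interval", lab))
  }
  # the planted log2 means reproduce the target ratio exactly
  rc <- tr$class != "PARENT_EQUAL"
  realized <- (tr$f1_log2 - (tr$p1_log2 + tr$p2_log2) / 2) /
    abs(tr$p1_log2 - tr$p2_log2)
  expect_equal(realized[rc], tr$d_over_a_target[rc], tolerance = 1e-9)
  # parental gap respects the configured minimum
  expect_true(all(abs(tr$p1_log2 - tr$p2_log2)[rc] >= cfg$min_parent_gap - 1e-9))
  # noiseless limit: classifying the planted means recovers every label
  lab_hat <- classify_mode(tr$d_over_a_target[rc])
  expect_equal(as.character(lab_hat), tr$class[rc])
})

test_that("simulated group means converge to the configured means", {
  cfg <- triad_sim_config(n_genes = 60, n_replicates = 200, dispersion = 0.05,
                          baseline_log_sd = 0.5, seed = 30)
  sim <- simulate_triad_counts(cfg)
  cols <- sim$samples$sample[sim$samples$population == "P1" &
                               sim$samples$condition == "control"]
  est <- rowMeans(sim$counts[, cols])
  expected <- 2^sim$truth$p1_log2
  expect_true(all(abs(est / expected - 1) < 0.02 + 3 * sqrt(0.05 + 1 / expected) / sqrt(200)))
  # population totals are balanced by construction
  tot <- vapply(c("p1_log2", "p2_log2", "f1_log2"), function(col) {
    sum(2^sim$truth[[col]])
  }, numeric(1))
  expect_lt(max(abs(log(tot / mean(tot)))), 1e-6)
})

test_that("cardiac generator produces exact two-segment signals", {
  cfg <- cardiac_sim_config(true_abt_celsius = 32, noise_sd = 0, seed = 3)
  sim <- simulate_cardiac_trace(cfg)
  expect_true(all(diff(sim$trace$temp_c) > 0))
  expect_true(all(sim$trace$bpm > 0))
  s <- arrhenius_transform(sim$trace)
  left <- s$temp_c <= 32
  fl <- lm(y ~ x, data = s[left, ]); fr <- lm(y ~ x, data = s[!left, ])
  expect_lt(sum(resid(fl)^2) + sum(resid(fr)^2), 1e-20)
  expect_equal(unname(coef(fl)[2]), cfg$slope_left, tolerance = 1e-9)
  expect_equal(unname(coef(fr)[2]), cfg$slope_right, tolerance = 1e-9)
  # reproducibility with noise
  n1 <- simulate_cardiac_trace(cardiac_sim_config(seed = 9))
  n2 <- simulate_cardiac_trace(cardiac_sim_config(seed = 9))
  expect_identical(n1, n2)
  expect_error(cardiac_sim_config(true_abt_celsius = 50), "inside")
})

test_that("splice generator plants divergence and is reproducible", {
  cfg <- splice_sim_config(n_events = 400, seed = 3)
  a <- simulate_splice_events(cfg)
  b <- simulate_splice_events(cfg)
  expect_identical(a, b)
  ev <- a$events
  cnt_cols <- grep("^[IS]_", names(ev), value = TRUE)
  expect_true(all(as.matrix(ev[cnt_cols]) >= 0))
  expect_true(all(as.matrix(ev[cnt_cols]) == floor(as.matrix(ev[cnt_cols]))))
  # planted condition-mean difference equals the configured magnitude
  tr <- a$truth
  expect_equal(tr$psi_ctrl[tr$divergent] - tr$psi_heat[tr$divergent],
               tr$true_delta_psi[tr$divergent])
  expect_true(all(abs(tr$true_delta_psi[tr$divergent]) == cfg$true_delta_psi))
  expect_true(all(tr$psi_ctrl >= 0 & tr$psi_ctrl <= 1))
  expect_true(all(tr$psi_heat >= 0 & tr$psi_heat <= 1))
  # type mix within multinomial sampling error
  p_se <- mean(ev$type == "SE")
  expect_lt(abs(p_se - 0.91), 3 * sqrt(0.91 * 0.09 / 400) + 1e-9)
  expect_error(splice_sim_config(true_delta_psi = 1.5), "true_delta_psi")
  expect_error(splice_sim_config(type_mix = c(SE = 0.5, MXE = 0.2)), "sum to 1")
})

test_that("high-depth planted events all clear the divergence threshold", {
  cfg <- splice_sim_config(n_events = 300, read_depth = 20000,
                           psi_concentration = 5000, divergent_fraction = 0.2,
                           true_delta_psi = 0.3, seed = 12)
  sim <- simulate_splice_events(cfg)
  tested <- test_events(sim$events)
  planted <- tested[sim$truth$divergent, ]
  expect_true(all(abs(planted$delta_psi) >= 0.1))
  expect_true(all(abs(planted$delta_psi - sim$truth$true_delta_psi[sim$truth$divergent]) < 0.05))
})
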