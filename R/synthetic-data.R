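# Ground-truth-labelled synthetic data for every pipeline stage.
#
# The generators emulate the study design the pipeline was built for:
# two parental populations (P1, P2) and their F1 hybrid, each measured in
# a control and a heat condition with replicated bulk RNA-seq; cardiac
# heart-rate ramps that are piecewise linear in Arrhenius coordinates;
# and replicated junction-count tables for alternative-splicing events.

# Proportions of planted dominance classes. These follow the class
# frequencies observed among heat-condition genes of a hybrid abalone
# triad (ODO dominating at ~37%, UDO ~26%, additive ~7%).
default_class_proportions <- function() {
  n <- c(ADD = 1457, HPD = 1119, LPD = 1278, ODO = 8235,
         UDO = 5819, PPD = 2047, NPD = 2014)
  n / sum(n)
}

# Table-1 intervals with the unbounded tails truncated at |d/|a|| = 3.
mode_target_intervals <- function() {
  list(UDO = c(-3, -1.2), LPD = c(-1.2, -0.8), NPD = c(-0.8, -0.2),
       ADD = c(-0.2, 0.2), PPD = c(0.2, 0.8), HPD = c(0.8, 1.2),
       ODO = c(1.2, 3))
}

# Planted targets are drawn from the central half of each interval
# (margin = 25% of the width on each side) so that recovery under
# replicate noise is well-defined; boundary genes are inherently
# ambiguous at finite depth.
TARGET_MARGIN <- 0.25
# Parental log2 gap above the configured minimum, uniform spread.
GAP_SPREAD <- 5
# Cap on the hybrid's planted deviation from the mid-parent,
# |target| * gap, in log2 units. Keeps simulated expression within a
# realistic dynamic range: without it, strongly overdominant genes with
# wide parental gaps would reach astronomically large means and dominate
# the library.
MAX_HYBRID_DEVIATION <- 6

#' Configuration for the triad count simulator
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per population x condition (3 is the
#'   usual bulk design).
#' @param baseline_log_mean,baseline_log_sd Normal distribution of
#'   per-gene baseline expression on the log2 scale.
#' @param dispersion Negative-binomial dispersion shared across genes
#'   (`variance = mu + dispersion * mu^2`); must be > 0.
#' @param class_proportions Named proportions over the dominance classes
#'   (`ADD, PPD, NPD, HPD, LPD, ODO, UDO`, optionally `PARENT_EQUAL`);
#'   must sum to 1.
#' @param library_size_factors Per-sample positive scalars multiplying
#'   expected counts (length `6 * n_replicates`), default all 1.
#' @param min_parent_gap Minimum |P1 - P2| log2 expression gap for
#'   ratio-classifiable genes.
#' @param de_fraction,de_log2fc Optional planted control-vs-heat effect:
#'   fraction of genes shifted (in every population, so dominance classes
#'   are preserved under heat) and the log2 magnitude of the shift
#'   (sign randomized per gene).
#' @param seed RNG seed; generation is fully reproducible given the
#'   config.
#' @return A validated `triad_sim_config` list.
#' @export
triad_sim_config <- function(n_genes = 2000, n_replicates = 3,
                             baseline_log_mean = 8, baseline_log_sd = 1.5,
                             dispersion = 0.05,
                             class_proportions = default_class_proportions(),
                             library_size_factors = NULL,
                             min_parent_gap = 1.0,
                             de_fraction = 0, de_log2fc = 0,
                             seed = 1) {
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  assert_that(is_count(n_replicates), "n_replicates must be a positive integer")
  assert_that(is_scalar_number(dispersion) && dispersion > 0,
              "dispersion must be > 0")
  assert_that(is_scalar_number(min_parent_gap) && min_parent_gap >= 0,
              "min_parent_gap must be >= 0")
  assert_that(is_scalar_number(baseline_log_sd) && baseline_log_sd >= 0,
              "baseline_log_sd must be >= 0")
  known <- c(names(mode_target_intervals()), "PARENT_EQUAL")
  assert_that(!is.null(names(class_proportions)) &&
                all(names(class_proportions) %in% known),
              "class_proportions must be named with the dominance classes")
  assert_that(abs(sum(class_proportions) - 1) <= 1e-9,
              "class_proportions must sum to 1 (got %.12f)", sum(class_proportions))
  assert_that(all(class_proportions >= 0), "class_proportions must be non-negative")
  n_samples <- 6 * n_replicates
  if (is.null(library_size_factors)) library_size_factors <- rep(1, n_samples)
  assert_that(length(library_size_factors) == n_samples &&
                all(library_size_factors > 0),
              "library_size_factors must be %d positive scalars", n_samples)
  assert_that(is_scalar_number(de_fraction) && de_fraction >= 0 && de_fraction <= 1,
              "de_fraction must be in [0, 1]")
  cfg <- list(n_genes = as.integer(n_genes), n_replicates = as.integer(n_replicates),
              baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
              dispersion = dispersion, class_proportions = class_proportions,
              library_size_factors = library_size_factors,
              min_parent_gap = min_parent_gap,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              seed = as.integer(seed))
  class(cfg) <- "triad_sim_config"
  cfg
}

#' Simulate hybrid-parent triad counts with planted dominance classes
#'
#' Draws per-gene log2 baseline expression, a parental gap of at least
#' `min_parent_gap` log2 units (random direction), and a d/|a| target
#' from the planted class interval; the hybrid log2 mean is placed at
#' `mid-parent + target * |gap|`. Counts are negative binomial around the
#' linear-scale means (times the per-sample library factor) with shared
#' dispersion. `PARENT_EQUAL` genes get a zero parental gap and a hybrid
#' mean at the common parental value. When `de_fraction > 0`, that
#' fraction of genes receives a log2 shift of `de_log2fc` (random sign)
#' in the heat condition of every population.
#'
#' Expected total expression is equalized across the three populations
#' by per-gene baseline shifts (which leave every planted ratio exact):
#' real transcriptomes conserve total output, and without the constraint
#' an over-dominance-heavy class mix would systematically inflate the
#' hybrid's library relative to the parents', making cross-population
#' normalization impossible for any method.
#'
#' The planted truth is expressed on the log2 expression scale; recover
#' it with `classify_matrix(..., normalization = "log2")`.
#'
#' @param config A [triad_sim_config()].
#' @return List with `counts` (integer matrix, genes x samples),
#'   `samples` (sample sheet: `sample, population, condition,
#'   replicate`), and `truth` (`data.frame`: `gene, class,
#'   d_over_a_target` (`NA` for `PARENT_EQUAL`), `p1_log2, p2_log2,
#'   f1_log2` (control-condition log2 means), `de` flag,
#'   `de_log2fc` signed shift).
#' @export
simulate_triad_counts <- function(config) {
  assert_that(inherits(config, "triad_sim_config"),
              "config must come from triad_sim_config()")
  withr::with_seed(config$seed, simulate_triad_counts_impl(config))
}

simulate_triad_counts_impl <- function(cfg) {
  n <- cfg$n_genes
  intervals <- mode_target_intervals()
  props <- cfg$class_proportions
  labels <- sample(names(props), n, replace = TRUE, prob = props)

  target <- rep(NA_real_, n)
  for (lab in names(intervals)) {
    idx <- which(labels == lab)
    if (!length(idx)) next
    iv <- intervals[[lab]]
    m <- TARGET_MARGIN * diff(iv)
    target[idx] <- stats::runif(length(idx), iv[1] + m, iv[2] - m)
  }

  baseline <- stats::rnorm(n, cfg$baseline_log_mean, cfg$baseline_log_sd)
  gap <- stats::runif(n, cfg$min_parent_gap, cfg$min_parent_gap + GAP_SPREAD)
  # shrink the gap of extreme-ratio genes so the hybrid deviation
  # |target| * gap stays within the dynamic-range cap (never below the
  # configured minimum gap)
  cap <- ifelse(is.na(target) | abs(target) < 1e-12, Inf,
                MAX_HYBRID_DEVIATION / abs(target))
  gap <- pmin(gap, pmax(cap, cfg$min_parent_gap))
  gap <- gap * sample(c(-1, 1), n, replace = TRUE)
  gap[labels == "PARENT_EQUAL"] <- 0

  p1 <- baseline + gap / 2
  p2 <- baseline - gap / 2
  f1 <- ifelse(labels == "PARENT_EQUAL", baseline, baseline + target * abs(gap))

  # Equalize expected total expression across the three populations by
  # per-gene baseline shifts. A shift common to P1, P2 and F1 leaves the
  # planted d/|a| ratio of the gene untouched, so the truth is exact,
  # while equal totals emulate conservation of total transcript output —
  # without it the hybrid's library would dwarf the parents' whenever
  # over-dominant genes outnumber under-dominant ones, and no library
  # normalization could place the populations on a common scale.
  shift <- balance_population_totals(cbind(p1, p2, f1))
  p1 <- p1 + shift; p2 <- p2 + shift; f1 <- f1 + shift

  de <- stats::runif(n) < cfg$de_fraction
  de_shift <- ifelse(de, cfg$de_log2fc * sample(c(-1, 1), n, replace = TRUE), 0)

  pops <- c("P1", "P2", "F1")
  conds <- c("control", "heat")
  reps <- seq_len(cfg$n_replicates)
  samples <- expand.grid(replicate = reps, condition = conds, population = pops,
                         stringsAsFactors = FALSE)[, c("population", "condition", "replicate")]
  samples$sample <- sprintf("%s_%s_%d", samples$population,
                            ifelse(samples$condition == "control", "C", "H"),
                            samples$replicate)
  samples <- samples[, c("sample", "population", "condition", "replicate")]

  log2_mean <- cbind(P1 = p1, P2 = p2, F1 = f1)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(sprintf("gene_%05d", seq_len(n)), samples$sample))
  for (j in seq_len(nrow(samples))) {
    m <- log2_mean[, samples$population[j]]
    if (samples$condition[j] == "heat") m <- m + de_shift
    mu <- 2^m * cfg$library_size_factors[j]
    counts[, j] <- as.integer(stats::rnbinom(n, mu = mu, size = 1 / cfg$dispersion))
  }

  truth <- data.frame(
    gene = rownames(counts),
    class = labels,
    d_over_a_target = target,
    p1_log2 = p1, p2_log2 = p2, f1_log2 = f1,
    de = de, de_log2fc = de_shift,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(counts = counts, samples = samples, truth = truth)
}

# Per-gene log2 shifts that equalize the population totals of a
# linear-scale expression matrix (columns = populations). Multiplying a
# gene by a constant scales its contribution to every population, so a
# multiplicative reweighting can match the column totals while
# preserving all within-gene contrasts exactly. Damped fixed-point
# iteration on the log scale; the shift vector is re-anchored to mean
# zero every step (only relative totals matter, and an anchor stops the
# overall level from drifting) and clamped so no single gene moves more
# than a few log2 units away from its drawn baseline.
balance_population_totals <- function(mat_log2, max_iter = 5000, tol = 1e-12,
                                      damp = 0.7, max_shift = 3) {
  M <- 2^mat_log2
  s <- rep(0, nrow(M)) # ln-scale shift
  bound <- max_shift * log(2)
  for (it in seq_len(max_iter)) {
    A <- exp(s) * M
    tot <- colSums(A)
    target <- exp(mean(log(tot)))
    if (max(abs(log(tot / target))) < tol) break
    w <- A / rowSums(A)
    s <- s + damp * as.vector(w %*% log(target / tot))
    s <- s - mean(s)
    s <- pmin(pmax(s, -bound), bound)
  }
  s / log(2)
}

#' Configuration for the cardiac-trace simulator
#'
#' The noiseless signal is exactly two line segments in Arrhenius
#' coordinates (ln rate vs 1000/K) meeting at the true break
#' temperature; Gaussian noise is added on the ln(rate) scale, the scale
#' on which the break regression operates. Defaults mimic a ramp raised
#' at 0.1 degC per step from 20 degC with a Q10-like warming slope
#' before the break and a sharp decline after it.
#'
#' @param true_abt_celsius True break temperature (degC), strictly
#'   inside the ramp.
#' @param temp_start,temp_end Ramp range (degC).
#' @param resolution Ramp step (degC per sample).
#' @param slope_left,slope_right Segment slopes of ln(rate) vs 1000/K
#'   (the left segment covers temperatures below the break, i.e. larger
#'   1000/K). Equal slopes produce a collinear, break-free trace for
#'   degeneracy testing.
#' @param ln_rate_at_break ln(beats/min) at the break.
#' @param noise_sd Gaussian noise SD on ln(rate); >= 0.
#' @param seed RNG seed.
#' @export
cardiac_sim_config <- function(true_abt_celsius = 32, temp_start = 20,
                               temp_end = 38, resolution = 0.1,
                               slope_left = -6, slope_right = 30,
                               ln_rate_at_break = log(90),
                               noise_sd = 0.05, seed = 1) {
  assert_that(temp_start < true_abt_celsius && true_abt_celsius < temp_end,
              "true_abt_celsius must lie strictly inside [temp_start, temp_end]")
  assert_that(is_scalar_number(resolution) && resolution > 0,
              "resolution must be > 0")
  assert_that(is_scalar_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  cfg <- list(true_abt_celsius = true_abt_celsius, temp_start = temp_start,
              temp_end = temp_end, resolution = resolution,
              slope_left = slope_left, slope_right = slope_right,
              ln_rate_at_break = ln_rate_at_break,
              noise_sd = noise_sd, seed = as.integer(seed))
  class(cfg) <- "cardiac_sim_config"
  cfg
}

#' Simulate a cardiac heart-rate ramp with a known Arrhenius break
#'
#' @param config A [cardiac_sim_config()].
#' @return List with `trace` (`data.frame`: `temp_c` strictly
#'   increasing, `bpm` positive) and `truth` (list: `abt_celsius`,
#'   `x_break`, segment slopes).
#' @export
simulate_cardiac_trace <- function(config) {
  assert_that(inherits(config, "cardiac_sim_config"),
              "config must come from cardiac_sim_config()")
  temp <- seq(config$temp_start, config$temp_end, by = config$resolution)
  assert_that(all(diff(temp) > 0), "temperature grid must be strictly increasing")
  x <- 1000 / (temp + 273.15)
  x_break <- 1000 / (config$true_abt_celsius + 273.15)
  # left segment: T <= ABT, i.e. x >= x_break
  y <- ifelse(x >= x_break,
              config$ln_rate_at_break + config$slope_left * (x - x_break),
              config$ln_rate_at_break + config$slope_right * (x - x_break))
  if (config$noise_sd > 0) {
    y <- y + withr::with_seed(config$seed,
                              stats::rnorm(length(y), 0, config$noise_sd))
  }
  list(
    trace = data.frame(temp_c = temp, bpm = exp(y)),
    truth = list(abt_celsius = config$true_abt_celsius, x_break = x_break,
                 slope_left = config$slope_left, slope_right = config$slope_right)
  )
}

#' Configuration for the splice-event simulator
#'
#' @param n_events Number of events.
#' @param n_replicates Replicates per condition.
#' @param type_mix Named proportions over event types
#'   (`SE, MXE, A5SS, A3SS, RI`); default reflects a transcriptome where
#'   skipped exons dominate (91%) over mutually exclusive exons (9%).
#' @param psi_shape1,psi_shape2 Beta parameters of the baseline
#'   (control) event-level \eqn{\psi}.
#' @param psi_concentration Beta concentration of replicate-level
#'   \eqn{\psi} around the condition mean (larger = tighter replicates).
#' @param divergent_fraction Fraction of events planted as truly
#'   divergent.
#' @param true_delta_psi Magnitude of the planted
#'   control-minus-heat \eqn{\Delta\psi} (sign randomized per event);
#'   `|true_delta_psi| <= 1`.
#' @param read_depth Mean junction read depth per sample (Poisson).
#' @param len_inclusion,len_skipping Effective lengths of the inclusion
#'   and skipping forms (>= 1).
#' @param seed RNG seed.
#' @export
splice_sim_config <- function(n_events = 1000, n_replicates = 3,
                              type_mix = c(SE = 0.91, MXE = 0.09,
                                           A5SS = 0, A3SS = 0, RI = 0),
                              psi_shape1 = 2, psi_shape2 = 2,
                              psi_concentration = 100,
                              divergent_fraction = 0.1,
                              true_delta_psi = 0.3,
                              read_depth = 200,
                              len_inclusion = 2, len_skipping = 1,
                              seed = 1) {
  assert_that(is_count(n_events), "n_events must be a positive integer")
  assert_that(is_count(n_replicates) && n_replicates >= 2,
              "n_replicates must be an integer >= 2")
  assert_that(!is.null(names(type_mix)) && all(names(type_mix) %in% SPLICE_TYPES),
              "type_mix must be named with event types %s",
              paste(SPLICE_TYPES, collapse = "/"))
  assert_that(abs(sum(type_mix) - 1) <= 1e-9, "type_mix must sum to 1")
  assert_that(psi_shape1 > 0 && psi_shape2 > 0 && psi_concentration > 0,
              "psi distribution parameters must be positive")
  assert_that(is_scalar_number(true_delta_psi) && abs(true_delta_psi) <= 1,
              "|true_delta_psi| must be <= 1")
  assert_that(divergent_fraction >= 0 && divergent_fraction <= 1,
              "divergent_fraction must be in [0, 1]")
  assert_that(is_scalar_number(read_depth) && read_depth >= 0,
              "read_depth must be >= 0")
  assert_that(len_inclusion >= 1 && len_skipping >= 1,
              "effective lengths must be >= 1")
  cfg <- list(n_events = as.integer(n_events), n_replicates = as.integer(n_replicates),
              type_mix = type_mix, psi_shape1 = psi_shape1, psi_shape2 = psi_shape2,
              psi_concentration = psi_concentration,
              divergent_fraction = divergent_fraction,
              true_delta_psi = true_delta_psi, read_depth = read_depth,
              len_inclusion = len_inclusion, len_skipping = len_skipping,
              seed = as.integer(seed))
  class(cfg) <- "splice_sim_config"
  cfg
}

#' Simulate replicated splice-event junction-count tables
#'
#' Each event gets a control-condition \eqn{\psi} from the baseline Beta
#' distribution; planted divergent events shift the heat condition by
#' the configured \eqn{\Delta\psi} (control minus heat, random sign,
#' the control \eqn{\psi} being moved into the feasible window when
#' necessary). Replicate \eqn{\psi} values are Beta-distributed around
#' the condition mean, junction depths Poisson, and inclusion counts
#' binomial given depth with the length-normalized inclusion
#' probability.
#'
#' @param config A [splice_sim_config()].
#' @return List with `events` (wide table: `event_id, gene_id, type,
#'   I_ctrl_*, S_ctrl_*, I_heat_*, S_heat_*, len_inclusion,
#'   len_skipping`) and `truth` (`data.frame`: `event_id, divergent,
#'   true_delta_psi` (signed; 0 for null events), `psi_ctrl,
#'   psi_heat`).
#' @export
simulate_splice_events <- function(config) {
  assert_that(inherits(config, "splice_sim_config"),
              "config must come from splice_sim_config()")
  withr::with_seed(config$seed, simulate_splice_events_impl(config))
}

simulate_splice_events_impl <- function(cfg) {
  n <- cfg$n_events
  type <- sample(names(cfg$type_mix), n, replace = TRUE, prob = cfg$type_mix)
  # several events can share a gene, so gene-level roll-ups are exercised
  gene_pool <- sprintf("sgene_%05d", seq_len(max(1L, ceiling(0.85 * n))))
  gene <- sample(gene_pool, n, replace = TRUE)

  psi_ctrl <- stats::rbeta(n, cfg$psi_shape1, cfg$psi_shape2)
  divergent <- stats::runif(n) < cfg$divergent_fraction
  dd <- ifelse(divergent, cfg$true_delta_psi * sample(c(-1, 1), n, replace = TRUE), 0)
  # keep both condition means inside [0.02, 0.98]
  lo <- 0.02 + pmax(0, dd)
  hi <- 0.98 + pmin(0, dd)
  psi_ctrl <- pmin(pmax(psi_ctrl, lo), hi)
  psi_heat <- psi_ctrl - dd

  r <- cfg$n_replicates
  kappa <- cfg$psi_concentration
  draw_cond <- function(mu, prefix) {
    icols <- matrix(0L, n, r); scols <- matrix(0L, n, r)
    for (k in seq_len(r)) {
      psi_rep <- stats::rbeta(n, mu * kappa, (1 - mu) * kappa)
      depth <- stats::rpois(n, cfg$read_depth)
      theta <- psi_rep * cfg$len_inclusion /
        (psi_rep * cfg$len_inclusion + (1 - psi_rep) * cfg$len_skipping)
      icols[, k] <- stats::rbinom(n, depth, theta)
      scols[, k] <- depth - icols[, k]
    }
    colnames(icols) <- sprintf("I_%s_%d", prefix, seq_len(r))
    colnames(scols) <- sprintf("S_%s_%d", prefix, seq_len(r))
    cbind(as.data.frame(icols), as.data.frame(scols))
  }
  events <- cbind(
    data.frame(event_id = sprintf("ev_%05d", seq_len(n)),
               gene_id = gene, type = type, stringsAsFactors = FALSE),
    draw_cond(psi_ctrl, "ctrl"),
    draw_cond(psi_heat, "heat"),
    data.frame(len_inclusion = cfg$len_inclusion, len_skipping = cfg$len_skipping)
  )
  truth <- data.frame(event_id = events$event_id, divergent = divergent,
                      true_delta_psi = dd, psi_ctrl = psi_ctrl,
                      psi_heat = psi_heat, stringsAsFactors = FALSE)
  list(events = events, truth = truth)
}
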