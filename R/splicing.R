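# Percent-spliced-in (psi) computation and the splice-divergence filter.

SPLICE_TYPES <- c("SE", "MXE", "A5SS", "A3SS", "RI")

#' Percent spliced in from junction counts
#'
#' Length-normalized inclusion fraction of an alternative-splicing event:
#' \deqn{\psi = (I/l_I) / (I/l_I + S/l_S)}
#' where `I` and `S` are inclusion- and skipping-junction read counts and
#' `lI`, `lS` the effective lengths of the inclusion and skipping forms.
#' Length normalization corrects for the inclusion isoform spanning more
#' junctions; raw counts would bias \eqn{\psi} upward. Events with no
#' coverage (`I = S = 0`) have undefined \eqn{\psi} and return `NA`.
#'
#' @param I,S Non-negative integer vectors of inclusion/skipping counts.
#' @param lI,lS Effective lengths (>= 1), scalars or vectors.
#' @return Numeric vector of \eqn{\psi} values in `[0, 1]`, `NA` where
#'   `I + S = 0`.
#' @examples
#' compute_psi(30, 10, lI = 2, lS = 1)  # 0.6
#' compute_psi(5, 0, lI = 2, lS = 1)    # 1
#' compute_psi(0, 0, lI = 2, lS = 1)    # NA
#' @export
compute_psi <- function(I, S, lI, lS) {
  assert_that(all(is.finite(I)) && all(is.finite(S)) && all(I >= 0) && all(S >= 0),
              "junction counts must be non-negative")
  assert_that(all(lI >= 1) && all(lS >= 1), "effective lengths must be >= 1")
  num <- I / lI
  den <- num + S / lS
  ifelse(I + S == 0, NA_real_, num / den)
}

# Pull the per-replicate inclusion/skipping columns of an event table.
# Wide layout: I_ctrl_1.., S_ctrl_1.., I_heat_1.., S_heat_1..
event_count_cols <- function(events, what = c("I", "S"),
                             condition = c("ctrl", "heat")) {
  what <- match.arg(what); condition <- match.arg(condition)
  cols <- grep(sprintf("^%s_%s_\\d+$", what, condition), names(events), value = TRUE)
  cols[order(as.integer(sub(".*_", "", cols)))]
}

# Per-replicate psi matrices and shared event metadata.
event_psi_matrices <- function(events) {
  for (need in c("event_id", "gene_id", "type", "len_inclusion", "len_skipping")) {
    assert_that(need %in% names(events), "event table lacks column '%s'", need)
  }
  psi_for <- function(cond) {
    icols <- event_count_cols(events, "I", cond)
    scols <- event_count_cols(events, "S", cond)
    assert_that(length(icols) >= 1 && length(icols) == length(scols),
                "unbalanced or missing %s junction-count columns", cond)
    I <- as.matrix(events[icols]); S <- as.matrix(events[scols])
    psi <- compute_psi(as.vector(I), as.vector(S),
                       rep(events$len_inclusion, times = ncol(I)),
                       rep(events$len_skipping, times = ncol(I)))
    list(psi = matrix(psi, nrow = nrow(events)), reads = I + S)
  }
  list(ctrl = psi_for("ctrl"), heat = psi_for("heat"))
}

#' Test events for control-vs-heat divergence in psi
#'
#' Computes per-replicate \eqn{\psi} values from junction counts, the
#' between-condition divergence \eqn{\Delta\psi} (mean control \eqn{\psi}
#' minus mean heat \eqn{\psi}), a per-event two-sample p-value on the
#' replicate \eqn{\psi} values, and Benjamini-Hochberg FDR across tested
#' events. This is a documented stand-in for a likelihood-based
#' differential-splicing model; it operates on replicate-level \eqn{\psi}
#' only.
#'
#' Methods: `"welch"` (default) is a Welch two-sample t-test;
#' `"permutation"` compares the observed `|mean difference|` against the
#' label-permutation distribution — exhaustive over all assignments when
#' there are at most `max_exhaustive` of them (always the case for 3-vs-3,
#' 20 assignments), otherwise Monte Carlo with `n_perm` draws under a
#' fixed seed.
#'
#' Events with fewer than 2 defined \eqn{\psi} per condition cannot be
#' tested; they are kept with `NA` p-values and counted in
#' `attr(result, "n_untestable")`.
#'
#' @param events Event table in wide layout: columns `event_id, gene_id,
#'   type, len_inclusion, len_skipping` and per-replicate counts
#'   `I_ctrl_1...`, `S_ctrl_1...`, `I_heat_1...`, `S_heat_1...`.
#' @param method `"welch"` or `"permutation"`.
#' @param n_perm Monte Carlo permutations when exhaustive enumeration is
#'   infeasible.
#' @param max_exhaustive Enumeration cutoff on the number of label
#'   assignments.
#' @param seed Seed for Monte Carlo permutations.
#' @return `events` augmented with `psi_ctrl, psi_heat, delta_psi,
#'   mean_reads` (mean of `I + S` over all samples), `p`, `fdr`.
#' @export
test_events <- function(events, method = c("welch", "permutation"),
                        n_perm = 2000, max_exhaustive = 10000, seed = 1) {
  method <- match.arg(method)
  mats <- event_psi_matrices(events)
  psi_c <- mats$ctrl$psi; psi_h <- mats$heat$psi
  n_c <- ncol(psi_c); n_h <- ncol(psi_h)
  testable <- rowSums(!is.na(psi_c)) >= 2 & rowSums(!is.na(psi_h)) >= 2

  p <- rep(NA_real_, nrow(events))
  if (method == "welch") {
    idx <- which(testable & rowSums(is.na(psi_c)) == 0 & rowSums(is.na(psi_h)) == 0)
    if (length(idx)) {
      res <- row_welch(psi_c[idx, , drop = FALSE], psi_h[idx, , drop = FALSE])
      p[idx] <- res$p
    }
    # events testable only with partial replicates: fall back per event
    rest <- which(testable)
    rest <- setdiff(rest, idx)
    for (i in rest) {
      a <- psi_c[i, ][!is.na(psi_c[i, ])]
      b <- psi_h[i, ][!is.na(psi_h[i, ])]
      p[i] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
  } else {
    for (i in which(testable)) {
      a <- psi_c[i, ][!is.na(psi_c[i, ])]
      b <- psi_h[i, ][!is.na(psi_h[i, ])]
      p[i] <- permutation_p(a, b, n_perm = n_perm,
                            max_exhaustive = max_exhaustive,
                            seed = seed + i)
    }
  }

  out <- events
  out$psi_ctrl <- rowMeans(psi_c, na.rm = TRUE)
  out$psi_heat <- rowMeans(psi_h, na.rm = TRUE)
  out$delta_psi <- out$psi_ctrl - out$psi_heat
  out$mean_reads <- rowMeans(cbind(mats$ctrl$reads, mats$heat$reads))
  out$p <- p
  out$fdr <- NA_real_
  out$fdr[testable] <- stats::p.adjust(p[testable], method = "BH")
  attr(out, "n_untestable") <- sum(!testable)
  out
}

# Two-sided permutation p-value for the difference in group means.
# Exhaustive over all choose(n, n_a) label assignments (observed
# included) when feasible, Monte Carlo otherwise.
permutation_p <- function(a, b, n_perm = 2000, max_exhaustive = 10000, seed = 1) {
  pool <- c(a, b)
  n <- length(pool); n_a <- length(a)
  obs <- abs(mean(a) - mean(b))
  tot <- sum(pool)
  stat_for <- function(idx) {
    ma <- sum(pool[idx]) / n_a
    mb <- (tot - sum(pool[idx])) / (n - n_a)
    abs(ma - mb)
  }
  if (choose(n, n_a) <= max_exhaustive) {
    stats_all <- utils::combn(n, n_a, stat_for)
    mean(stats_all >= obs - 1e-12)
  } else {
    draws <- withr::with_seed(seed, {
      replicate(n_perm, stat_for(sample.int(n, n_a)))
    })
    (1 + sum(draws >= obs - 1e-12)) / (n_perm + 1)
  }
}

#' Filter splice events on coverage, divergence, and FDR
#'
#' Keeps events with mean junction reads strictly greater than
#' `min_mean_reads` (the coverage filter is exclusive: a mean of exactly
#' 5 is dropped), `|delta_psi| >= dpsi_cut` (inclusive), and
#' `FDR < fdr_cut`. Untested events (missing FDR) are excluded and
#' counted in a warning.
#'
#' @param events Output of [test_events()] (columns `delta_psi`,
#'   `mean_reads`, `fdr` required).
#' @param min_mean_reads Coverage threshold, exclusive (default 5).
#' @param dpsi_cut Divergence threshold, inclusive (default 0.1).
#' @param fdr_cut FDR threshold, exclusive (default 0.05).
#' @return The surviving rows, with attributes `type_counts` (events
#'   kept per event type) and `n_genes` (distinct genes among kept
#'   events).
#' @export
filter_events <- function(events, min_mean_reads = 5, dpsi_cut = 0.1, fdr_cut = 0.05) {
  for (need in c("delta_psi", "mean_reads", "fdr")) {
    assert_that(need %in% names(events),
                "events lack column '%s'; run test_events() first", need)
  }
  untested <- is.na(events$fdr)
  if (any(untested)) {
    warning(sprintf("%d untested event(s) (missing FDR) excluded", sum(untested)))
  }
  keep <- !untested &
    events$mean_reads > min_mean_reads &
    abs(events$delta_psi) >= dpsi_cut &
    events$fdr < fdr_cut
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "type_counts") <- table(factor(out$type, levels = SPLICE_TYPES))
  attr(out, "n_genes") <- length(unique(out$gene_id))
  out
}
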