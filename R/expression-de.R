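# TMM normalization and the control-vs-heat differential-expression
# stand-in.
#
# The DE test here is deliberately NOT a negative-binomial GLM: it is a
# Welch two-sample test on log2(CPM + 0.5). Downstream stages only
# consume gene sets, and the stand-in keeps the pipeline free of a heavy
# model while preserving the published significance thresholds
# (BH FDR < 0.05 and |log2FC| > 1).

#' Trimmed mean of M-values (TMM) normalization
#'
#' Computes per-sample scaling factors by the doubly-trimmed weighted
#' mean of M-values (log2 expression ratios) against a reference sample,
#' then counts-per-million on the rescaled library sizes. M-values are
#' trimmed symmetrically (`trim_m`, default 30%) and A-values
#' (average log intensities) likewise (`trim_a`, default 5%); the
#' surviving M-values are averaged with inverse delta-method variance
#' weights. Factors are rescaled so their geometric mean is 1.
#'
#' The reference is the column whose library size is closest to the mean
#' library size, unless `ref_column` is given.
#'
#' @param counts Integer matrix, genes x samples (column names required).
#' @param trim_m Fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a Fraction of A-values trimmed from each tail (default 0.05).
#' @param ref_column Optional reference column (index or name).
#' @return Object of class `normalized_matrix`: list with `cpm`
#'   (genes x samples matrix on the counts-per-million scale), `factors`
#'   (named, geometric mean 1), `lib_size`, and `ref_column`.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization
#'   method for differential expression analysis of RNA-seq data.
#'   Genome Biology 11:R25.
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05, ref_column = NULL) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2, "need at least 2 samples")
  assert_that(all(is.finite(counts)) && all(counts >= 0), "counts must be non-negative")
  lib_size <- colSums(counts)
  zero_lib <- colnames(counts)[lib_size == 0]
  assert_that(length(zero_lib) == 0,
              "all-zero sample(s): %s", paste(zero_lib, collapse = ", "))
  expressed <- rowSums(counts > 0) > 0
  assert_that(any(expressed), "no expressed gene in the matrix")
  x <- counts[expressed, , drop = FALSE]

  if (is.null(ref_column)) {
    ref <- which.min(abs(lib_size - mean(lib_size)))
  } else {
    ref <- if (is.character(ref_column)) match(ref_column, colnames(counts)) else ref_column
    assert_that(!is.na(ref) && ref >= 1 && ref <= ncol(counts),
                "ref_column not found in counts")
  }
  f <- vapply(seq_len(ncol(x)), function(i) {
    tmm_factor(x[, i], x[, ref], lib_size[i], lib_size[ref],
               trim_m = trim_m, trim_a = trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f))) # geometric mean 1
  names(f) <- colnames(counts)

  eff <- lib_size * f
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  out <- list(cpm = cpm, factors = f, lib_size = lib_size, ref_column = ref)
  class(out) <- "normalized_matrix"
  out
}

# Scaling factor of one observation column against the reference column.
# Doubly-trimmed, precision-weighted mean of M-values on the log2 scale.
tmm_factor <- function(obs, ref, n_obs, n_ref, trim_m = 0.30, trim_a = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  log_r <- log2((obs / n_obs) / (ref / n_ref))          # M-values
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2  # A-values
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(log_r) & is.finite(abs_e)
  log_r <- log_r[fin]; abs_e <- abs_e[fin]; v <- v[fin]
  if (length(log_r) == 0 || max(abs(log_r)) < 1e-6) return(1)
  n <- length(log_r)
  lo_l <- floor(n * trim_m) + 1; hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1; hi_s <- n + 1 - lo_s
  keep <- rank(log_r) >= lo_l & rank(log_r) <= hi_l &
          rank(abs_e) >= lo_s & rank(abs_e) <= hi_s
  f <- sum(log_r[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("TMM-normalized matrix: %d genes x %d samples (reference column %d)\n",
              nrow(x$cpm), ncol(x$cpm), x$ref_column))
  print(round(x$factors, 4))
  invisible(x)
}

#' Call differential expression between control and heat (stand-in test)
#'
#' Within one population, tests each gene for a control-vs-heat shift
#' with a Welch two-sample t-test on `log2(CPM + 0.5)` and adjusts
#' p-values across genes by Benjamini-Hochberg. A gene is flagged
#' significant when `FDR < fdr_cut` and `|log2FC| > lfc_cut`
#' (defaults 0.05 and 1). The log2 fold-change is the difference of
#' group means of `log2(CPM + 0.5)`, heat minus control.
#'
#' This is a documented stand-in for a count-model (negative binomial)
#' differential-expression fit; it is adequate for planted-effect
#' recovery and set-level integration, not for reference DE inference.
#'
#' @param norm A `normalized_matrix` from [tmm_normalize()].
#' @param samples Sample sheet (`sample`, `population`, `condition`,
#'   `replicate`).
#' @param population Population to contrast (`"P1"`, `"P2"` or `"F1"`).
#' @param fdr_cut,lfc_cut Significance thresholds.
#' @return `data.frame` with columns `gene, log2fc, p, fdr, significant,
#'   direction` (`up`/`down`/`none`, heat relative to control).
#' @export
call_degs <- function(norm, samples, population, fdr_cut = 0.05, lfc_cut = 1.0) {
  assert_that(inherits(norm, "normalized_matrix"), "norm must come from tmm_normalize()")
  samples <- validate_samples(samples, colnames(norm$cpm))
  sel <- samples[samples$population == population, , drop = FALSE]
  assert_that(nrow(sel) > 0, "population '%s' absent from sample sheet", population)
  ctrl <- sel$sample[sel$condition == "control"]
  heat <- sel$sample[sel$condition == "heat"]
  assert_that(length(ctrl) >= 2 && length(heat) >= 2,
              "need >= 2 replicates per condition for population '%s' (control: %d, heat: %d)",
              population, length(ctrl), length(heat))
  expr <- log2(norm$cpm + 0.5)
  res <- row_welch(expr[, heat, drop = FALSE], expr[, ctrl, drop = FALSE])
  fdr <- stats::p.adjust(res$p, method = "BH")
  sig <- fdr < fdr_cut & abs(res$diff) > lfc_cut
  data.frame(
    gene = rownames(norm$cpm),
    log2fc = res$diff,
    p = res$p,
    fdr = fdr,
    significant = sig,
    direction = ifelse(!sig, "none", ifelse(res$diff > 0, "up", "down")),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
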