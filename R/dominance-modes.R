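# Hybrid expression-mode classification from the d/|a| dominance ratio.

# Class intervals on the d/|a| axis. The negative overdominance interval
# is (-Inf, -1.2): the two dominance directions are symmetric about 0 and
# the seven intervals tile the real line.
MODE_LEVELS <- c("UDO", "LPD", "NPD", "ADD", "PPD", "HPD", "ODO", "PARENT_EQUAL")

#' Dominance-to-additivity ratio d/|a| of hybrid expression
#'
#' For each gene, the deviation of hybrid expression from the mid-parent
#' value, scaled by the parental expression gap:
#' \deqn{d/|a| = (F_1 - \mu) / |P_1 - P_2|, \quad \mu = (P_1 + P_2)/2}
#' where `P1` and `P2` are the two parental group means and `F1` the
#' hybrid group mean, all on a common expression scale. Under the
#' `half_gap` convention the denominator is `|P1 - P2| / 2` (the classical
#' additive effect `|a|`), so `half_gap` ratios are exactly twice the
#' `full_gap` ratios.
#'
#' Genes whose parents are (numerically) equally expressed,
#' `|P1 - P2| < epsilon`, have no defined ratio and return `NA`; they are
#' reported as `PARENT_EQUAL` by [classify_matrix()] rather than being
#' forced through a near-zero denominator.
#'
#' @param p1,p2 Numeric vectors of parental group means.
#' @param f1 Numeric vector of hybrid group means.
#' @param convention `"full_gap"` (denominator `|P1 - P2|`, the default) or
#'   `"half_gap"` (denominator `|P1 - P2| / 2`).
#' @param epsilon Positive scalar; parental gaps below this are treated as
#'   parent-equal (ratio `NA`).
#' @return Numeric vector of ratios, `NA` where the parents are equal.
#' @examples
#' compute_d_over_a(14, 10, 14)           # 0.5: hybrid at the high parent
#' compute_d_over_a(14, 10, 12)           # 0: hybrid at the mid-parent
#' compute_d_over_a(10, 10, 15)           # NA: parents equal
#' @seealso [classify_mode()], [classify_matrix()]
#' @export
compute_d_over_a <- function(p1, p2, f1,
                             convention = c("full_gap", "half_gap"),
                             epsilon = 1e-8) {
  convention <- match.arg(convention)
  assert_that(is.numeric(p1) && is.numeric(p2) && is.numeric(f1),
              "p1, p2 and f1 must be numeric")
  n <- length(f1)
  assert_that(length(p1) == n && length(p2) == n,
              "p1, p2 and f1 must have equal length")
  assert_that(all(is.finite(p1)) && all(is.finite(p2)) && all(is.finite(f1)),
              "expression means must be finite")
  assert_that(is_scalar_number(epsilon) && epsilon > 0,
              "epsilon must be a positive number")
  gap <- abs(p1 - p2)
  denom <- if (convention == "half_gap") gap / 2 else gap
  mu <- (p1 + p2) / 2
  ratio <- ifelse(gap < epsilon, NA_real_, (f1 - mu) / denom)
  ratio
}

#' Classify a d/|a| ratio into a hybrid expression mode
#'
#' Maps ratios to the seven dominance classes. Intervals (closed/open ends
#' exactly as stated):
#'
#' | label | class                      | interval         |
#' |-------|----------------------------|------------------|
#' | UDO   | under-dominance            | (-Inf, -1.2)     |
#' | LPD   | low-parent dominance       | \[-1.2, -0.8)    |
#' | NPD   | negative partial dominance | \[-0.8, -0.2)    |
#' | ADD   | additive                   | \[-0.2, 0.2\]    |
#' | PPD   | positive partial dominance | (0.2, 0.8\]      |
#' | HPD   | high-parent dominance      | (0.8, 1.2\]      |
#' | ODO   | over-dominance             | (1.2, Inf)       |
#'
#' The positive direction is the high-parent side, the negative direction
#' the low-parent side. The intervals partition the real line: every
#' finite ratio receives exactly one label.
#'
#' @param ratio Numeric vector of d/|a| ratios (finite; `NaN`/`NA` is an
#'   error — parent-equal genes are handled upstream).
#' @return Factor with levels `UDO, LPD, NPD, ADD, PPD, HPD, ODO`.
#' @examples
#' classify_mode(c(-2, -1.2, -0.5, 0.2, 0.5, 1.2, 1.3))
#' @export
classify_mode <- function(ratio) {
  assert_that(is.numeric(ratio) && length(ratio) >= 1, "ratio must be numeric")
  assert_that(!anyNA(ratio), "ratio contains NA/NaN; classify_mode requires finite ratios")
  lab <- ifelse(ratio < -1.2, "UDO",
         ifelse(ratio < -0.8, "LPD",
         ifelse(ratio < -0.2, "NPD",
         ifelse(ratio <= 0.2, "ADD",
         ifelse(ratio <= 0.8, "PPD",
         ifelse(ratio <= 1.2, "HPD", "ODO"))))))
  factor(lab, levels = MODE_LEVELS[1:7])
}

#' Per-gene mode calls from a count matrix
#'
#' Computes population group means for one condition on a normalized
#' scale, forms the d/|a| ratio and classifies every detected gene.
#' Populations are coded `P1` (maternal parent), `P2` (paternal parent)
#' and `F1` (hybrid) in the sample sheet.
#'
#' Normalization: `"tmm_linear"` (default) takes group means of TMM-scaled
#' counts-per-million; `"log2"` takes group means of `log2(CPM + 0.5)`
#' with plain library-size (total-count) CPM, i.e. classifies on the
#' log2 expression scale. The log2 path deliberately does not apply TMM:
#' TMM assumes most genes are unchanged between the samples being
#' scaled, which holds within a population but is violated between
#' populations exactly when most genes are non-additive — the situation
#' this classification exists to measure. Total-count scaling instead
#' assumes conservation of total transcript output across populations.
#' The scale matters because the ratio is not invariant under log
#' transformation; the chosen scale is recorded in the result.
#'
#' Genes with zero counts in every sample of the condition are dropped as
#' undetected and listed in `attr(result, "undetected")`.
#'
#' @param counts Integer matrix, genes x samples, with gene ids as row
#'   names and sample ids as column names.
#' @param samples Sample sheet `data.frame` with columns
#'   `sample`, `population` (`P1`/`P2`/`F1`), `condition`
#'   (`control`/`heat`), `replicate`.
#' @param condition Condition to classify, `"control"` or `"heat"`.
#' @param convention,epsilon Passed to [compute_d_over_a()].
#' @param normalization `"tmm_linear"` or `"log2"` (see Details).
#' @return `data.frame` with columns `gene, p1, p2, f1, mid_parent,
#'   ratio, label, convention, scale`; `label` includes `PARENT_EQUAL`
#'   for genes with no defined ratio. Attribute `undetected` holds the
#'   dropped gene ids.
#' @export
classify_matrix <- function(counts, samples,
                            condition = c("control", "heat"),
                            convention = c("full_gap", "half_gap"),
                            normalization = c("tmm_linear", "log2"),
                            epsilon = 1e-8) {
  condition <- match.arg(condition)
  convention <- match.arg(convention)
  normalization <- match.arg(normalization)
  samples <- validate_samples(samples, colnames(counts))
  sel <- samples[samples$condition == condition, , drop = FALSE]
  missing_pop <- setdiff(c("P1", "P2", "F1"), unique(sel$population))
  assert_that(length(missing_pop) == 0,
              "condition '%s' is missing population(s): %s",
              condition, paste(missing_pop, collapse = ", "))
  sub <- counts[, sel$sample, drop = FALSE]

  detected <- rowSums(sub) > 0
  undetected <- rownames(sub)[!detected]
  sub <- sub[detected, , drop = FALSE]
  assert_that(nrow(sub) > 0, "no gene detected in condition '%s'", condition)

  expr <- if (normalization == "log2") {
    cpm0 <- sweep(sub, 2, colSums(sub), "/") * 1e6
    log2(cpm0 + 0.5)
  } else {
    tmm_normalize(sub)$cpm
  }
  group_mean <- function(pop) {
    cols <- sel$sample[sel$population == pop]
    rowMeans(expr[, cols, drop = FALSE])
  }
  p1 <- group_mean("P1"); p2 <- group_mean("P2"); f1 <- group_mean("F1")
  ratio <- compute_d_over_a(p1, p2, f1, convention = convention, epsilon = epsilon)
  label <- rep("PARENT_EQUAL", length(ratio))
  ok <- !is.na(ratio)
  label[ok] <- as.character(classify_mode(ratio[ok]))
  out <- data.frame(
    gene = rownames(sub),
    p1 = p1, p2 = p2, f1 = f1,
    mid_parent = (p1 + p2) / 2,
    ratio = ratio,
    label = factor(label, levels = MODE_LEVELS),
    convention = convention,
    scale = normalization,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "undetected") <- undetected
  out
}

#' Summarize mode calls into class counts and percentages
#'
#' Counts genes per dominance class and reports (i) the non-additive share
#' of detected genes and (ii) per-class shares. Non-additive genes are all
#' detected genes that are neither `ADD` nor `PARENT_EQUAL`. Percentages
#' are rounded half-up to two decimals, matching how such tables are
#' conventionally printed.
#'
#' @param calls Result of [classify_matrix()], or a factor/character
#'   vector of labels.
#' @param denominator Denominator for the per-class percentages:
#'   `"non_additive"` (default; shares of non-additively expressed genes)
#'   or `"detected"` (shares of all classified genes).
#' @return Object of class `mode_summary`: list with `counts` (named
#'   integer vector over all labels), `n_detected`, `n_non_additive`,
#'   `pct_non_additive`, `class_pct` (named, over `denominator`), and
#'   `denominator`.
#' @examples
#' calls <- factor(rep(c("ADD", "ODO", "UDO"), c(10, 25, 15)),
#'                 levels = heterosiskit:::MODE_LEVELS)
#' summarize_modes(calls)
#' @export
summarize_modes <- function(calls, denominator = c("non_additive", "detected")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(calls)) calls <- calls$label
  if (!is.factor(calls)) calls <- factor(as.character(calls), levels = MODE_LEVELS)
  assert_that(length(calls) > 0, "no mode calls to summarize")
  assert_that(!anyNA(calls), "calls contain labels outside the known classes")
  counts <- table(calls)
  n_detected <- length(calls)
  n_non_additive <- n_detected - counts[["ADD"]] - counts[["PARENT_EQUAL"]]
  denom_n <- if (denominator == "non_additive") n_non_additive else n_detected
  class_pct <- if (denom_n > 0) {
    round_half_up(100 * as.numeric(counts) / denom_n, 2)
  } else {
    rep(0, length(counts))
  }
  names(class_pct) <- names(counts)
  out <- list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    n_detected = n_detected,
    n_non_additive = as.integer(n_non_additive),
    pct_non_additive = round_half_up(100 * n_non_additive / n_detected, 2),
    class_pct = class_pct,
    denominator = denominator
  )
  class(out) <- "mode_summary"
  out
}

#' @export
print.mode_summary <- function(x, ...) {
  cat(sprintf("Hybrid expression modes: %d genes classified\n", x$n_detected))
  cat(sprintf("Non-additive: %d (%.2f%%)\n", x$n_non_additive, x$pct_non_additive))
  cat(sprintf("Class shares (of %s genes):\n",
              if (x$denominator == "non_additive") "non-additive" else "detected"))
  show <- x$counts > 0
  df <- data.frame(class = names(x$counts)[show],
                   n = x$counts[show],
                   pct = sprintf("%.2f", x$class_pct[show]),
                   row.names = NULL)
  print(df, right = FALSE)
  invisible(x)
}
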