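# Internal helpers shared across modules.

# Round half away from zero (commercial rounding). base::round() rounds
# half to even, which does not reproduce percentage tables that were
# rounded half-up.
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Stop unless `cond` holds; message is sprintf-formatted.
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Row-wise Welch two-sample t-test on matrices (genes x replicates).
# Returns two-sided p-values and the mean difference (a - b).
# Degenerate rows (both groups constant): p = 1 when the means agree,
# p = 0 when they differ (the t statistic diverges).
row_welch <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0
  if (any(zero)) p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  list(p = p, diff = ma - mb, t = tstat, df = df)
}

pkg_version <- function() {
  as.character(utils::packageVersion("heterosiskit"))
}

# Header comment stamped on every table the package writes.
output_header <- function(seed = NA, params = list()) {
  ser <- paste(deparse(params, control = "all"), collapse = "")
  chars <- utf8ToInt(ser)
  hash <- sprintf("%08x", bitwAnd(sum(chars * seq_along(chars)) %% .Machine$integer.max, 0x7fffffff))
  c(
    sprintf("# heterosiskit %s", pkg_version()),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# params_hash: %s", hash)
  )
}

# Write a data.frame as TSV with the package's comment header.
write_tsv_stamped <- function(df, path, seed = NA, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(seed = seed, params = params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
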