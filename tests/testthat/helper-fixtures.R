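# Shared fixtures, built in code at test time.

# Small deterministic NB count matrix for normalization tests.
make_nb_matrix <- function(n_genes = 500, n_samples = 6, seed = 42,
                           mu_log_mean = 5, mu_log_sd = 1, size = 10) {
  withr::with_seed(seed, {
    mu <- exp(rnorm(n_genes, mu_log_mean, mu_log_sd))
    m <- sapply(seq_len(n_samples), function(j) rnbinom(n_genes, mu = mu, size = size))
    dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%d", seq_len(n_samples)))
    m
  })
}

# Minimal triad sample sheet for hand-built count matrices.
make_triad_samples <- function(n_replicates = 3) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      condition = c("control", "heat"),
                      population = c("P1", "P2", "F1"),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_%d", grid$population,
                         ifelse(grid$condition == "control", "C", "H"),
                         grid$replicate)
  grid[, c("sample", "population", "condition", "replicate")]
}

# Independent brute-force two-segment fit: lm() per side over every
# admissible split. Used as the oracle for fit_breakpoint.
brute_force_breakpoint <- function(series, min_segment = 3) {
  n <- nrow(series)
  splits <- seq.int(min_segment, n - min_segment)
  rss <- vapply(splits, function(i) {
    left <- lm(y ~ x, data = series[1:i, ])
    right <- lm(y ~ x, data = series[(i + 1):n, ])
    sum(resid(left)^2) + sum(resid(right)^2)
  }, numeric(1))
  best <- which.min(rss)
  list(break_index = splits[best], rss = rss[best], profile = rss)
}

# Independent TMM factor computation, written directly from the
# published algorithm (trim M and A, precision-weighted mean), for the
# dual-route check against tmm_normalize().
brute_force_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  counts <- counts[rowSums(counts > 0) > 0, , drop = FALSE]
  lib <- colSums(counts)
  one_factor <- function(j) {
    o <- counts[, j] / lib[j]
    r <- counts[, ref] / lib[ref]
    keep <- o > 0 & r > 0
    M <- log2(o[keep] / r[keep])
    A <- (log2(o[keep]) + log2(r[keep])) / 2
    w <- 1 / ((lib[j] - counts[keep, j]) / (lib[j] * counts[keep, j]) +
              (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref]))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    sel <- rank(M) >= lo_m & rank(M) <= hi_m & rank(A) >= lo_a & rank(A) <= hi_a
    2^(sum(M[sel] * w[sel]) / sum(w[sel]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f / exp(mean(log(f)))
}

# Exhaustive permutation p-value by direct enumeration over index
# subsets (independent of the package's combn-based routine).
enumerate_permutation_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L; total <- 0L
  for (bits in 0:(2^n - 1)) {
    idx <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
    if (length(idx) != na) next
    total <- total + 1L
    stat <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}
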