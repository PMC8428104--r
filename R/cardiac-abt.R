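# Arrhenius break temperature (ABT) estimation from cardiac traces.

#' Arrhenius transform of a cardiac trace
#'
#' Maps a heart-rate ramp to Arrhenius coordinates: `x = 1000 / (T + 273.15)`
#' (inverse absolute temperature, 1000/K) and `y = ln(rate)` with rate in
#' beats per minute. Because `x` decreases as temperature increases, the
#' series is strictly decreasing in `x` when the ramp is strictly
#' increasing in temperature.
#'
#' @param trace `data.frame` with columns `temp_c` (degrees Celsius,
#'   strictly increasing) and `bpm` (beats per minute, strictly positive).
#' @return `data.frame` of class `arrhenius_series` with columns
#'   `x` (1000/K), `y` (ln bpm) and `temp_c` (carried along so the break
#'   can be reported back in degrees Celsius).
#' @examples
#' tr <- data.frame(temp_c = c(20, 25, 30), bpm = c(40, 55, 60))
#' arrhenius_transform(tr)
#' @export
arrhenius_transform <- function(trace) {
  assert_that(is.data.frame(trace) && all(c("temp_c", "bpm") %in% names(trace)),
              "trace must be a data.frame with columns temp_c and bpm")
  temp <- trace$temp_c; rate <- trace$bpm
  assert_that(length(temp) == length(rate), "temp_c and bpm differ in length")
  assert_that(all(diff(temp) > 0), "temperatures must be strictly increasing")
  bad <- which(!(is.finite(rate) & rate > 0))
  assert_that(length(bad) == 0,
              "non-positive heart rate at index %s", paste(bad, collapse = ", "))
  out <- data.frame(x = 1000 / (temp + 273.15), y = log(rate), temp_c = temp)
  class(out) <- c("arrhenius_series", "data.frame")
  out
}

# Residual sum of squares of the OLS line through points (x[i..j], y[i..j]),
# plus slope/intercept. Closed form; exact for collinear input.
ols_segment <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) { # vertical stack of points: fit the mean
    return(list(slope = 0, intercept = my, rss = sum((y - my)^2)))
  }
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  rss <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, rss = rss)
}

#' Fit a two-segment Arrhenius regression and locate the break
#'
#' Exhaustively searches every admissible split of the series into a
#' left (cooler) and right (warmer) segment, fits each side by ordinary
#' least squares, and returns the split minimizing the total residual sum
#' of squares. The two lines are free (no continuity constraint at the
#' break). The Arrhenius break temperature (ABT) is reported as the
#' temperature of the last point of the left segment, i.e. the warmest
#' point before the regime change. Ties in total RSS are broken toward
#' the lower temperature.
#'
#' When the RSS profile over candidate splits is flat within
#' `1e-9 * total sum of squares` — e.g. perfectly collinear data, which
#' any split fits equally well — there is no distinguishable break and
#' the fit is flagged `degenerate` (the reported ABT is then meaningless).
#'
#' @param series An `arrhenius_series` from [arrhenius_transform()], or a
#'   trace `data.frame` with `temp_c`/`bpm` columns (transformed
#'   automatically).
#' @param min_segment Minimum number of points per segment (default 3;
#'   two points fit any line exactly, which would produce spurious
#'   zero-RSS segments).
#' @return Object of class `breakpoint_fit`: list with `abt_celsius`,
#'   `break_index` (last left-segment point), `left`/`right`
#'   (slope, intercept, rss per segment), `rss` (total), `rss_profile`
#'   (`data.frame`: `break_index`, `temp_c`, `rss`), `degenerate`, `n`.
#' @examples
#' cfg <- cardiac_sim_config(true_abt_celsius = 31, noise_sd = 0)
#' sim <- simulate_cardiac_trace(cfg)
#' fit_breakpoint(arrhenius_transform(sim$trace))$abt_celsius
#' @export
fit_breakpoint <- function(series, min_segment = 3) {
  if (!inherits(series, "arrhenius_series")) {
    assert_that(is.data.frame(series) && all(c("temp_c", "bpm") %in% names(series)),
                "series must be an arrhenius_series or a trace with temp_c/bpm")
    series <- arrhenius_transform(series)
  }
  assert_that(is_count(min_segment) && min_segment >= 2,
              "min_segment must be an integer >= 2")
  n <- nrow(series)
  assert_that(n >= 2 * min_segment,
              "need at least %d points for min_segment = %d (got %d)",
              2 * min_segment, min_segment, n)
  x <- series$x; y <- series$y; temp <- series$temp_c

  splits <- seq.int(min_segment, n - min_segment)
  fits <- lapply(splits, function(i) {
    l <- ols_segment(x[1:i], y[1:i])
    r <- ols_segment(x[(i + 1):n], y[(i + 1):n])
    list(left = l, right = r, rss = l$rss + r$rss)
  })
  rss_profile <- vapply(fits, `[[`, numeric(1), "rss")
  best <- which.min(rss_profile) # first minimum = lowest temperature on ties
  i <- splits[best]

  tss <- sum((y - mean(y))^2)
  degenerate <- diff(range(rss_profile)) < 1e-9 * max(tss, .Machine$double.eps)

  out <- list(
    abt_celsius = temp[i],
    break_index = i,
    left = fits[[best]]$left,
    right = fits[[best]]$right,
    rss = fits[[best]]$rss,
    rss_profile = data.frame(break_index = splits,
                             temp_c = temp[splits],
                             rss = rss_profile),
    degenerate = degenerate,
    n = n
  )
  class(out) <- "breakpoint_fit"
  out
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("Two-segment Arrhenius fit (%d points)\n", x$n))
  if (x$degenerate) {
    cat("Degenerate: RSS profile is flat, no distinguishable break.\n")
  } else {
    cat(sprintf("ABT: %.2f degC (break after point %d)\n", x$abt_celsius, x$break_index))
  }
  cat(sprintf("Slopes (y vs 1000/K): left %.3f, right %.3f; total RSS %.4g\n",
              x$left$slope, x$right$slope, x$rss))
  invisible(x)
}

#' Plot a two-segment Arrhenius fit
#'
#' Arrhenius plot (ln rate vs 1000/K) with the two fitted segments and
#' the estimated break temperature.
#'
#' @param x A `breakpoint_fit`.
#' @param series The `arrhenius_series` the fit was computed from.
#' @param ... Passed to [plot()].
#' @export
plot.breakpoint_fit <- function(x, series, ...) {
  plot(series$x, series$y, xlab = "1000/K", ylab = "ln(beats/min)", ...)
  i <- x$break_index
  xs <- series$x
  lines(xs[1:i], x$left$intercept + x$left$slope * xs[1:i], col = "firebrick", lwd = 2)
  lines(xs[(i + 1):x$n], x$right$intercept + x$right$slope * xs[(i + 1):x$n],
        col = "steelblue", lwd = 2)
  abline(v = series$x[i], lty = 2)
  if (!x$degenerate) {
    mtext(sprintf("ABT = %.2f degC", x$abt_celsius), side = 3, line = 0.2)
  }
  invisible(x)
}

#' Compare ABT estimates between groups by one-way ANOVA
#'
#' Classical fixed-effects one-way ANOVA of per-individual ABT values
#' across populations, plus all pairwise differences of group means in
#' degrees Celsius.
#'
#' @param abts_by_group Named list of numeric vectors (one per group,
#'   each with at least 2 values), or a `data.frame` with columns
#'   `group` and `abt_celsius`.
#' @return List with `f` (ANOVA F statistic), `p`, `df` (numerator,
#'   denominator), `means` (named group means), and `pairwise`
#'   (`data.frame`: `group_a`, `group_b`, `difference` = mean(a) - mean(b),
#'   for every ordered pair).
#' @examples
#' compare_abt_groups(list(DD = c(30.2, 31.1), SS = c(31.5, 32.2),
#'                         SD = c(32.1, 32.7)))
#' @export
compare_abt_groups <- function(abts_by_group) {
  if (is.data.frame(abts_by_group)) {
    assert_that(all(c("group", "abt_celsius") %in% names(abts_by_group)),
                "data.frame input needs columns group and abt_celsius")
    abts_by_group <- split(abts_by_group$abt_celsius, abts_by_group$group)
  }
  assert_that(is.list(abts_by_group) && length(abts_by_group) >= 2,
              "need at least 2 groups")
  assert_that(!is.null(names(abts_by_group)) && all(nzchar(names(abts_by_group))),
              "groups must be named")
  sizes <- lengths(abts_by_group)
  assert_that(all(sizes >= 2), "every group needs at least 2 values (empty or singleton group)")
  values <- unlist(abts_by_group, use.names = FALSE)
  group <- factor(rep(names(abts_by_group), sizes), levels = names(abts_by_group))
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f) && tab[["Sum Sq"]][1] == 0) { # zero between-group variation
    f <- 0; p <- 1
  }
  means <- vapply(abts_by_group, mean, numeric(1))
  pairs <- expand.grid(group_a = names(means), group_b = names(means),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$group_a != pairs$group_b, , drop = FALSE]
  pairs$difference <- means[pairs$group_a] - means[pairs$group_b]
  rownames(pairs) <- NULL
  list(f = f, p = p, df = tab$Df, means = means, pairwise = pairs)
}
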