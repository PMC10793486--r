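#' Exact sign test for paired differences
#'
#' Binomial test on the signs of the nonzero differences; zeros are
#' discarded per the standard convention. With no nonzero difference the
#' result is flagged degenerate with p = 1.
#'
#' @param differences Numeric vector of paired differences.
#' @param side `"greater"` (one-sided: positive median) or `"two"`.
#' @return A `fn_test` result: `statistic` (number of positive differences),
#'   `p_value`, `n` (nonzero differences), `test_name`, `sidedness`,
#'   `degenerate`.
#' @export
sign_test <- function(differences, side = c("greater", "two")) {
  side <- match.arg(side)
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) {
    return(fn_test(NA_real_, 1, 0, "sign", side, degenerate = TRUE))
  }
  k <- sum(d > 0)
  p <- if (side == "greater") {
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    stats::binom.test(k, n, 0.5, alternative = "two.sided")$p.value
  }
  fn_test(k, p, n, "sign", side)
}

#' Mood's median test for two or more groups
#'
#' Builds the 2 x k contingency table of counts above versus at-or-below the
#' pooled grand median (values equal to the median count as "below") and
#' applies a chi-squared test, by default without continuity correction.
#' Conservative and valid for groups with different sizes and variances.
#'
#' @param groups List of numeric vectors (k >= 2 groups).
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A `fn_test` with `statistic` (chi-squared), `p_value`, `n`
#'   (pooled size), plus the `table` used. Flagged degenerate when a group
#'   lies entirely on one side of the pooled median in a way that empties a
#'   table margin.
#' @export
median_test <- function(groups, correct = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  pooled <- unlist(groups)
  if (length(pooled) < 4) stop("pooled sample size must be at least 4")
  med <- stats::median(pooled)
  tab <- vapply(groups, function(g) {
    c(above = sum(g > med), below = sum(g <= med))
  }, numeric(2))
  degen <- any(rowSums(tab) == 0)
  if (degen) {
    out <- fn_test(NA_real_, 1, length(pooled), "median", "two",
                   degenerate = TRUE)
    out$table <- tab
    return(out)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out <- fn_test(unname(ct$statistic), unname(ct$p.value), length(pooled),
                 "median", "two")
  out$table <- tab
  out
}

#' Pearson correlation with interpretive band
#'
#' Standard Pearson r labeled with the band convention used throughout the
#' analyses: |r| < 0.2 uncorrelated, 0.2 <= |r| <= 0.5 weak-moderate,
#' |r| > 0.5 strong.
#'
#' @param x,y Numeric vectors (n >= 3, nonzero variance).
#' @return List with `r`, `band`, `n`, `defined` (`FALSE` when a variance is
#'   zero, in which case `r` is `NA`).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, band = "undefined", n = length(x),
                defined = FALSE))
  }
  r <- stats::cor(x, y)
  band <- if (abs(r) < 0.2) "uncorrelated" else if (abs(r) <= 0.5) {
    "weak-moderate"
  } else "strong"
  list(r = r, band = band, n = length(x), defined = TRUE)
}

fn_test <- function(statistic, p_value, n, test_name, sidedness,
                    degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 test_name = test_name, sidedness = sidedness,
                 degenerate = degenerate),
            class = "fn_test")
}

#' @export
print.fn_test <- function(x, ...) {
  cat(sprintf("%s test (%s-sided): statistic = %.4g, p = %.4g, n = %d%s\n",
              x$test_name, x$sidedness, x$statistic, x$p_value, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
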