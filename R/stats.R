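#' Percent change between two values
#'
#' `100 * (after - before) / before`, vectorised. Scale-invariant:
#' multiplying both values by a constant leaves the result unchanged.
#'
#' @param before Baseline value(s); must be strictly positive.
#' @param after Later value(s).
#' @return Percent change(s).
#' @examples
#' percent_change(40, 366) # 815
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0)) {
    abort("'before' must be strictly positive")
  }
  100 * (after - before) / before
}

#' One-sample t test against a null mean
#'
#' Classical one-sample t with a two-tailed p from the t distribution on
#' `n - 1` degrees of freedom. A zero-variance sample is returned as a
#' flagged degenerate row rather than an error.
#'
#' @param values Numeric sample (NAs dropped; at least 2 values).
#' @param mu Null mean (default 0).
#' @return A one-row tibble: `n`, `mean`, `se`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 values")
  m <- mean(values)
  s <- sd(values)
  if (s < 1e-12) {
    return(tibble(
      n = n, mean = m, se = 0, t = NA_real_, df = n - 1L, p = NA_real_,
      degenerate = TRUE
    ))
  }
  fit <- t.test(values, mu = mu)
  tibble(
    n = n, mean = m, se = s / sqrt(n),
    t = unname(fit$statistic), df = as.integer(unname(fit$parameter)),
    p = fit$p.value, degenerate = FALSE
  )
}

#' Paired t test between two periods
#'
#' Equivalent to a one-sample t test of the differences `after - before`
#' against 0. Zero-variance differences (including `after == before`) are
#' flagged degenerate.
#'
#' @param before,after Numeric vectors of equal length (pairs with an NA in
#'   either are dropped).
#' @return A one-row tibble as in [one_sample_t()], where `mean` is the
#'   mean difference.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) abort("'before' and 'after' must have equal length")
  keep <- !(is.na(before) | is.na(after))
  one_sample_t(after[keep] - before[keep], mu = 0)
}

#' Per-island percent changes with their contrast against no change
#'
#' Computes the percent change of a quantity between two periods for each
#' island and tests whether the mean change deviates from the null
#' expectation of 0 with a two-tailed one-sample t test. Summaries follow
#' the mean +/- SE convention.
#'
#' @param labels Island names.
#' @param before,after Values of the quantity in the two periods.
#' @return An object of class `change_summary`. [tidy()] returns the
#'   per-island changes, [glance()] the t-test row.
#' @examples
#' cs <- change_summary(c("i1", "i2", "i3"), c(10, 20, 40), c(30, 25, 80))
#' glance(cs)
#' @export
change_summary <- function(labels, before, after) {
  stopifnot(length(labels) == length(before), length(before) == length(after))
  pct <- percent_change(before, after)
  structure(
    list(
      per_island = tibble(island = as.character(labels), before = before,
                          after = after, change_pct = pct),
      test = one_sample_t(pct, mu = 0)
    ),
    class = "change_summary"
  )
}

#' @export
print.change_summary <- function(x, ...) {
  cat("<change_summary>\n")
  print(x$per_island)
  with(x$test, cat(sprintf(
    "mean change %.1f%% +/- %.1f (SE), t(%d) = %.2f, p = %.3f%s\n",
    mean, se, df, t, p, if (degenerate) " [degenerate]" else ""
  )))
  invisible(x)
}

#' @describeIn change_summary Per-island tibble of changes.
#' @param x A `change_summary`.
#' @param ... Unused.
#' @export
tidy.change_summary <- function(x, ...) x$per_island

#' @describeIn change_summary One-row tibble with the t test of the mean
#'   change against 0.
#' @export
glance.change_summary <- function(x, ...) x$test
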