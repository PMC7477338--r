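#' Bootstrapped standard error of the median
#'
#' Resamples the values with replacement `n_boot` times and reports the
#' sample median together with the standard deviation of the resampled
#' medians, the bootstrap standard error used for all cohort medians.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Number of bootstrap resamples (default 1000, >= 100).
#' @param seed Integer seed.
#' @return A tibble with `median`, `sem`, `n`, `n_boot`.
#' @export
bootstrap_median_sem <- function(values, n_boot = 1000, seed) {
  stopifnot(length(values) >= 2, n_boot >= 100)
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a single integer seed is required", call. = FALSE)
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2)
  set.seed(seed)
  meds <- vapply(seq_len(n_boot), function(i) {
    median(sample(values, replace = TRUE))
  }, double(1))
  tibble::tibble(median = median(values), sem = sd(meds),
                 n = length(values), n_boot = n_boot)
}

test_result <- function(test, statistic, df, n, p_value, estimate = NA_real_) {
  tibble::tibble(test = test, estimate = estimate, statistic = statistic,
                 df = df, n = n, p_value = p_value)
}

#' Nonparametric and regression tests used for cohort comparisons
#'
#' Thin, contract-checked wrappers around the standard R tests, returning
#' uniform one-row tibbles (`test`, `estimate`, `statistic`, `df`, `n`,
#' `p_value`):
#' * `kruskal_wallis(groups)` — comparison of several populations
#'   (`groups` a list of numeric vectors).
#' * `wilcoxon_signed_rank(x, y)` — paired comparison; zero differences
#'   are dropped per the standard signed-rank convention, and the exact
#'   distribution is used below n = 25 (normal approximation above).
#' * `chi_square_2x2(tab)` — association in a 2x2 count table, using the
#'   uncorrected statistic `sum((O - E)^2 / E)`.
#' * `shapiro_wilk(values)` — normality screen.
#'
#' @param groups List of >= 2 numeric vectors.
#' @param x,y Paired numeric vectors of equal length.
#' @param tab 2x2 matrix of counts.
#' @param values Numeric vector (3 to 5000 values).
#' @return A one-row tibble.
#' @name cohort_tests
NULL

#' @rdname cohort_tests
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 1)) stop("empty group", call. = FALSE)
  ht <- stats::kruskal.test(groups)
  test_result("Kruskal-Wallis", unname(ht$statistic),
              unname(ht$parameter), sum(lengths(groups)), ht$p.value)
}

#' @rdname cohort_tests
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[is.finite(d) & d != 0]
  if (length(d) < 1)
    stop("no non-zero paired differences", call. = FALSE)
  exact <- length(d) < 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("Wilcoxon signed-rank", unname(ht$statistic), NA_real_,
              length(d), ht$p.value)
}

#' @rdname cohort_tests
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (sum(tab) == 0) stop("empty table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("chi-square", unname(ht$statistic), unname(ht$parameter),
              sum(tab), ht$p.value)
}

#' @rdname cohort_tests
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  ht <- stats::shapiro.test(values)
  test_result("Shapiro-Wilk", unname(ht$statistic), NA_real_,
              length(values), ht$p.value)
}

#' Non-zero slope test
#'
#' Ordinary least-squares regression of `y` (or of the difference
#' `y - y2` when `y2` is supplied) on `x`, reporting the slope estimate
#' and the t-test of the hypothesis that the slope is zero.
#'
#' @param x Predictor, length >= 3, non-constant.
#' @param y Response.
#' @param y2 Optional second response; when given, the slope of `y - y2`
#'   against `x` is tested.
#' @return A one-row tibble (`test`, `estimate`, `statistic`, `df`, `n`,
#'   `p_value`).
#' @export
nonzero_slope_test <- function(x, y, y2 = NULL) {
  if (!is.null(y2)) {
    stopifnot(length(y) == length(y2))
    y <- y - y2
  }
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # summary.lm warns on residual-free data; an exactly constant response
  # is a legitimate input here (e.g. perfectly contrast-invariant ratios)
  co <- suppressWarnings(summary(fit))$coefficients
  test_result("non-zero slope", co["x", "t value"],
              fit$df.residual, length(x), co["x", "Pr(>|t|)"],
              estimate = co["x", "Estimate"])
}
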