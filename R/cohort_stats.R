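#' Predicted cumulative absorbed dose
#'
#' Extrapolation from cycle 1: the cycle-1 dose per unit activity times the
#' planned total administered activity (6 x 7.4 = 44.4 GBq at the study
#' defaults).
#'
#' @param d1_Gy_per_GBq Cycle-1 dose per unit activity, Gy/GBq (>= 0).
#' @param planned_total_GBq Planned total administered activity, GBq (>= 0).
#' @return Predicted cumulative dose, Gy.
#' @examples
#' predict_cumulative(0.43, 44.4) # ~19 Gy
#' @export
predict_cumulative <- function(d1_Gy_per_GBq, planned_total_GBq = 44.4) {
  if (any(d1_Gy_per_GBq < 0) || any(planned_total_GBq < 0)) {
    stop("invalid input: doses and activities must be >= 0", call. = FALSE)
  }
  d1_Gy_per_GBq * planned_total_GBq
}

#' Observed cumulative absorbed dose
#'
#' Sum of the per-cycle absorbed doses actually delivered.
#'
#' @param cycle_doses_Gy Non-empty numeric vector of per-cycle doses (>= 0).
#' @return Cumulative dose, Gy.
#' @export
observed_cumulative <- function(cycle_doses_Gy) {
  if (length(cycle_doses_Gy) == 0L) {
    stop("insufficient data: no per-cycle doses supplied", call. = FALSE)
  }
  if (any(cycle_doses_Gy < 0)) {
    stop("invalid input: per-cycle doses must be >= 0", call. = FALSE)
  }
  sum(cycle_doses_Gy)
}

#' Signed relative difference between predicted and observed means
#'
#' `100 * (predicted - observed) / observed`, so predicted above observed
#' gives a positive percentage.
#'
#' @param predicted_mean,observed_mean Cohort means; `observed_mean` > 0.
#' @return Percent difference.
#' @examples
#' relative_difference(19, 15) # +26.7
#' @export
relative_difference <- function(predicted_mean, observed_mean) {
  if (any(observed_mean <= 0)) {
    stop("undefined ratio: observed mean must be > 0", call. = FALSE)
  }
  100 * (predicted_mean - observed_mean) / observed_mean
}

#' Cohort summary (mean, SD, range)
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum,
#' the presentation used for per-cycle and cumulative dose tables.
#'
#' @param values Non-empty numeric vector.
#' @return A list of class `cohort_summary` with fields `n`, `mean`, `sd`,
#'   `min`, `max` and a `degenerate` flag when `n == 1` (SD reported as 0).
#' @export
cohort_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 1L) stop("insufficient data: empty summary input", call. = FALSE)
  degenerate <- n == 1L
  if (degenerate) {
    warning("single value: SD reported as 0", call. = FALSE)
  }
  structure(
    list(n = n, mean = mean(values),
         sd = if (degenerate) 0 else stats::sd(values),
         min = min(values), max = max(values), degenerate = degenerate),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("n=%d mean=%.3g (%.3g-%.3g), SD=%.3g\n",
              x$n, x$mean, x$min, x$max, x$sd))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p_raw)`.
#'
#' @param p_raw Raw p-value in \[0, 1\].
#' @param m Family size (>= 1).
#' @return Adjusted p-value.
#' @export
bonferroni <- function(p_raw, m) {
  if (any(p_raw < 0) || any(p_raw > 1)) {
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(m < 1)) stop("invalid input: m must be >= 1", call. = FALSE)
  pmin(1, m * p_raw)
}

#' Paired Hotelling T-squared test
#'
#' One-sample Hotelling test on the per-patient difference vectors
#' `d_i = predicted_i - observed_i` across the at-risk organs:
#' `T2 = n * dbar' Sigma^-1 dbar` with `Sigma` the sample covariance of the
#' differences, referred to `F(p, n - p)` via
#' `F = T2 (n - p) / (p (n - 1))`. The raw p-value is Bonferroni-adjusted
#' for `m_comparisons` tests.
#'
#' Differences that are zero to within numerical noise (relative to the scale
#' of the input doses) give `T2 = 0`, `p = 1` rather than an ill-conditioned
#' covariance solve.
#'
#' @param predicted,observed n x p numeric matrices (rows = patients,
#'   columns = organs), identically arranged.
#' @param m_comparisons Bonferroni family size.
#' @return A list of class `hotelling_result`: `t2`, `f_stat`, `df1`, `df2`,
#'   `p_raw`, `p_adjusted`, `n`, `organs`.
#' @export
hotelling_paired <- function(predicted, observed, m_comparisons = 5L) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed))) {
    stop("predicted and observed must have identical dimensions",
         call. = FALSE)
  }
  n <- nrow(predicted)
  p <- ncol(predicted)
  if (p < 1L) stop("need at least one organ column", call. = FALSE)
  if (n <= p) {
    stop("rank deficiency: need more patients (n = ", n,
         ") than organs (p = ", p, ")", call. = FALSE)
  }
  d <- predicted - observed
  scale <- max(abs(predicted), abs(observed), 1e-300)
  organs <- colnames(predicted)
  if (max(abs(d)) <= 1e-9 * scale) {
    t2 <- 0
    f_stat <- 0
    p_raw <- 1
  } else {
    dbar <- colMeans(d)
    sigma <- stats::cov(d)
    sol <- tryCatch(solve(sigma, dbar), error = function(e) NULL)
    if (is.null(sol)) {
      stop("singular covariance of differences; consider a smaller organ",
           " subset", call. = FALSE)
    }
    t2 <- n * sum(dbar * sol)
    f_stat <- t2 * (n - p) / (p * (n - 1))
    p_raw <- stats::pf(f_stat, p, n - p, lower.tail = FALSE)
  }
  structure(
    list(t2 = t2, f_stat = f_stat, df1 = p, df2 = n - p,
         p_raw = p_raw, p_adjusted = bonferroni(p_raw, m_comparisons),
         n = n, organs = organs),
    class = "hotelling_result"
  )
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf(
    "Hotelling T2 = %.4g, F(%d, %d) = %.4g, p = %.4g (adjusted %.4g), n = %d\n",
    x$t2, x$df1, x$df2, x$f_stat, x$p_raw, x$p_adjusted, x$n))
  invisible(x)
}
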