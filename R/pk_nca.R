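#' Noncompartmental analysis of a blood concentration curve
#'
#' Computes Cmax/Tmax from the observed maxima and the terminal elimination
#' rate (lambda_z) by log-linear regression over a terminal tail. Candidate
#' tails are the contiguous point sets ending at the last sample, of length
#' at least `min_tail`, starting strictly after Tmax; the tail maximizing
#' adjusted R-squared wins (ties by the longer tail). Pre-dose and very early
#' (< `t_min_h`) samples are excluded from the terminal fit.
#'
#' @param curve Data frame with columns `time_h` and `conc` (one patient,
#'   times unique); an optional logical `below_limit` column flags samples
#'   below the quantification limit, which are dropped.
#' @param min_tail Minimum number of terminal points (default 3).
#' @param t_min_h Samples at or before this time never enter the terminal
#'   fit (default 0.05 h, i.e. the immediate post-administration draw).
#' @return A list of class `nca_result`: `cmax`, `tmax_h`, `lambda_z_per_h`,
#'   `t_half_h`, `n_terminal_points`, `r_squared` (adjusted).
#' @examples
#' t <- c(1 / 3, 1, 2, 4, 24, 48, 72, 144)
#' nca(data.frame(time_h = t, conc = 2 * exp(-log(2) / 41.6 * t)))
#' @export
nca <- function(curve, min_tail = 3L, t_min_h = 0.05) {
  df <- as.data.frame(curve)
  stopifnot(!is.null(df$time_h), !is.null(df$conc))
  if (!is.null(df$below_limit)) df <- df[!df$below_limit, , drop = FALSE]
  if (anyDuplicated(df$time_h)) {
    stop("times must be unique within one patient", call. = FALSE)
  }
  df <- df[order(df$time_h), , drop = FALSE]
  if (!any(df$conc > 0)) {
    stop("insufficient data: no positive concentrations", call. = FALSE)
  }
  imax <- which.max(df$conc)
  cmax <- df$conc[imax]
  tmax <- df$time_h[imax]

  tail_df <- df[df$time_h > max(tmax, t_min_h) & df$conc > 0, , drop = FALSE]
  m <- nrow(tail_df)
  if (m < min_tail) {
    stop("insufficient data: fewer than ", min_tail,
         " usable post-peak points", call. = FALSE)
  }
  best <- NULL
  for (start in seq_len(m - min_tail + 1L)) {
    tt <- tail_df$time_h[start:m]
    lc <- log(tail_df$conc[start:m])
    k <- length(tt)
    fit <- stats::lm.fit(cbind(1, tt), lc)
    slope <- fit$coefficients[2L]
    rss <- sum(fit$residuals^2)
    tss <- sum((lc - mean(lc))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    adj <- if (k > 2L) 1 - (1 - r2) * (k - 1) / (k - 2) else r2
    if (slope < -1e-9 && (is.null(best) || adj > best$adj + 1e-12)) {
      best <- list(lambda_z = -slope, adj = adj, k = k)
    }
  }
  if (is.null(best)) {
    stop("no terminal phase: no tail with a negative log-linear slope",
         call. = FALSE)
  }
  structure(
    list(cmax = cmax, tmax_h = tmax,
         lambda_z_per_h = unname(best$lambda_z),
         t_half_h = log(2) / unname(best$lambda_z),
         n_terminal_points = best$k,
         r_squared = max(min(best$adj, 1), 0)),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "Cmax %.4g at %.3g h; lambda_z %.4g /h (t1/2 %.4g h, %d pts, adjR2 %.3f)\n",
    x$cmax, x$tmax_h, x$lambda_z_per_h, x$t_half_h, x$n_terminal_points,
    x$r_squared))
  invisible(x)
}

#' Geometric mean and geometric coefficient of variation
#'
#' `geomean = exp(mean(log v))`; `geo CV% = 100 * sqrt(exp(s^2) - 1)` with
#' `s` the sample SD of `log v`.
#'
#' @param values Positive numeric vector, length >= 2.
#' @return List with `geomean` and `geo_cv_percent`.
#' @export
geometric_summary <- function(values) {
  if (length(values) < 2L) {
    stop("insufficient data: need at least 2 values", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("invalid input: all values must be > 0", call. = FALSE)
  }
  lv <- log(values)
  s <- stats::sd(lv)
  list(geomean = exp(mean(lv)), geo_cv_percent = 100 * sqrt(exp(s^2) - 1))
}

#' Percent decline from a reference value
#'
#' `100 * (reference - later) / reference`.
#'
#' @param reference_value Reference (> 0).
#' @param later_value Later value.
#' @return Percent decline.
#' @export
percent_decline <- function(reference_value, later_value) {
  if (any(reference_value <= 0)) {
    stop("invalid input: reference must be > 0", call. = FALSE)
  }
  100 * (reference_value - later_value) / reference_value
}
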