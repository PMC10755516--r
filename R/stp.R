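#' Scale a cycle-1 time-integrated activity to a later cycle
#'
#' Later treatment cycles are imaged at a single time point (nominally 48 h,
#' 24 h permitted). The cycle-k time-integrated activity is obtained by
#' rescaling the whole cycle-1 curve shape by the ratio of the measured
#' cycle-k activity to the fitted cycle-1 activity at the same time
#' (activity-ratio method):
#' `tia_k = tia_c1 * activity_k(t) / A_c1_fitted(t)`.
#'
#' Under proportional kinetics (cycle-k curve an exact scalar multiple of
#' cycle 1) the method is exact.
#'
#' @param fit_c1 Cycle-1 `tac_fit` for the same patient/region.
#' @param tia_c1 Cycle-1 time-integrated activity, MBq.h.
#' @param time_h Measurement time of the later cycle, hours (> 0).
#' @param activity_MBq Measured activity at `time_h` (>= 0).
#' @param policy [tac_policy()]; its `activity_floor` (relative to the fitted
#'   initial activity) guards against division by a vanishing fitted value.
#'
#' @return The cycle-k time-integrated activity, MBq.h, with the scaling
#'   factor attached as attribute `"scale_factor"`.
#' @examples
#' nuc <- nuclide()
#' t <- c(2, 24, 48, 168)
#' fit <- fit_tac(data.frame(time_h = t, value = 100 * exp(-0.01 * t)), nuc)
#' t1 <- tia(fit)
#' scale_tia(fit, t1, 48, predict_tac(fit, 48) / 2) # == t1 / 2
#' @export
scale_tia <- function(fit_c1, tia_c1, time_h, activity_MBq,
                      policy = tac_policy()) {
  stopifnot(inherits(fit_c1, "tac_fit"))
  if (!is.numeric(time_h) || length(time_h) != 1L || time_h <= 0) {
    stop("single-time-point measurement must have time_h > 0", call. = FALSE)
  }
  if (!is.numeric(activity_MBq) || length(activity_MBq) != 1L ||
      activity_MBq < 0) {
    stop("single-time-point activity must be a non-negative number",
         call. = FALSE)
  }
  a_ref <- predict_tac(fit_c1, time_h)
  floor_abs <- policy$activity_floor * max(abs(fit_c1$terms$amplitude))
  if (!is.finite(a_ref) || a_ref <= floor_abs) {
    stop("unscalable: fitted cycle-1 activity at ", time_h,
         " h is at or below the floor (region ", fit_c1$region, ")",
         call. = FALSE)
  }
  factor <- activity_MBq / a_ref
  structure(tia_c1 * factor, scale_factor = factor)
}
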