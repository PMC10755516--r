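# Orchestration: cycle-1 curve fitting -> TIA -> single-time-point scaling
# for cycles 2+ -> MIRD dose engine -> cohort tables and Hotelling tests.

#' Fit all cycle-1 time-activity curves of a cohort
#'
#' Fits one curve per patient and imaging region (everything except blood)
#' from the cycle-1 rows of a measurements table and computes the
#' time-integrated activity and effective half-life of each.
#'
#' @param measurements An `activity_measurements` data frame (or anything
#'   [validate_measurements()] accepts).
#' @param nuclide A [nuclide()].
#' @param policy A [tac_policy()].
#' @param tia_mode `"analytic"` or `"hybrid"` (see [tia()]).
#' @return A list with `fits` (nested list `fits[[patient]][[region]]` of
#'   `tac_fit`s) and `log` (data frame: `patient_id`, `region`, `model`,
#'   `n_points`, `fit_quality`, `tia`, `tia_analytic`, `tia_hybrid`,
#'   `t_eff_h`, `clamped`).
#' @export
fit_cycle1 <- function(measurements, nuclide = rltdose::nuclide(),
                       policy = tac_policy(),
                       tia_mode = c("analytic", "hybrid")) {
  tia_mode <- match.arg(tia_mode)
  ms <- if (inherits(measurements, "activity_measurements")) measurements
        else validate_measurements(measurements)
  c1 <- ms[ms$cycle == 1L & ms$region != "blood", , drop = FALSE]
  if (!nrow(c1)) stop("no cycle-1 imaging measurements", call. = FALSE)
  fits <- list()
  rows <- list()
  for (pid in unique(c1$patient_id)) {
    sub_p <- c1[c1$patient_id == pid, , drop = FALSE]
    fits[[pid]] <- list()
    for (rg in unique(sub_p$region)) {
      sub <- sub_p[sub_p$region == rg, , drop = FALSE]
      fit <- fit_tac(sub, nuclide, policy)
      t_an <- tia(fit, "analytic")
      t_hy <- tia(fit, "hybrid", measurements = sub)
      fits[[pid]][[rg]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, region = rg, model = fit$model,
        n_points = fit$n_points, fit_quality = fit$fit_quality,
        tia = if (tia_mode == "analytic") t_an else t_hy,
        tia_analytic = t_an, tia_hybrid = t_hy,
        t_eff_h = effective_half_life(fit),
        clamped = fit$clamped, stringsAsFactors = FALSE
      )
    }
  }
  list(fits = fits, log = do.call(rbind, rows))
}

# blood concentration TIA (MBq.h/mL) for one patient from the cycle-1 blood
# rows; the pre-dose and immediate post-administration samples are excluded
# from the fit.
.blood_conc_tia <- function(blood_rows, nuclide, policy) {
  sub <- blood_rows[blood_rows$time_h >= 0.2 & blood_rows$value > 0, ,
                    drop = FALSE]
  fit <- fit_tac(sub, nuclide, policy)
  list(fit = fit, conc_tia = tia(fit, "analytic"))
}

#' Run the full dosimetry pipeline
#'
#' Executes the analysis end to end on a measurements table: cycle-1 curve
#' fits and time-integrated activities, remainder-of-body computation,
#' MIRD-schema organ doses (with sphere-model lacrimal self-dose and
#' blood-based red-marrow dose), single-time-point scaling for cycles 2+,
#' predicted and observed cumulative doses, per-organ cohort summaries with
#' relative differences, paired Hotelling T-squared comparisons per cycle,
#' and blood pharmacokinetic summaries. Deterministic given its inputs.
#'
#' @param measurements Measurements table (see [read_measurements()]).
#' @param S An [smatrix()]; defaults to the packaged fixture.
#' @param config A [run_config()].
#' @return A list of class `dosimetry_report`; see Details.
#'
#' @details The returned report contains:
#' \describe{
#'   \item{fit_log}{per patient/region cycle-1 fit summary (model choice,
#'     analytic and hybrid TIA, effective half-life).}
#'   \item{tia}{per patient/cycle/region TIA with the applied scale factor.}
#'   \item{doses}{per patient/cycle/organ `dose_Gy` and `d_Gy_per_GBq`.}
#'   \item{per_cycle}{cohort summaries of dose per unit activity for cycle 1
#'     and pooled cycles 2+.}
#'   \item{cumulative}{per-organ predicted (all cycle-1-evaluable patients)
#'     and observed (completers) cumulative-dose summaries and the signed
#'     relative difference of the means.}
#'   \item{cumulative_records}{per patient/organ predicted and, for
#'     completers, observed cumulative doses.}
#'   \item{hotelling}{one `hotelling_result` per cycle 2..planned, comparing
#'     predicted-through-k with observed-through-k on the at-risk organs.}
#'   \item{pk}{terminal-half-life geometric summary and per-patient NCA.}
#' }
#' @export
run_pipeline <- function(measurements, S = smatrix_lu177(),
                         config = run_config()) {
  stopifnot(inherits(S, "smatrix"), inherits(config, "run_config"))
  ms <- if (inherits(measurements, "activity_measurements")) measurements
        else validate_measurements(measurements)
  nuc <- config$nuclide
  policy <- config$tac_policy
  inj_GBq <- config$injected_GBq_per_cycle
  inj_MBq <- inj_GBq * 1000

  cf <- fit_cycle1(ms, nuc, policy, config$tia_mode)
  fits <- cf$fits
  flog <- cf$log

  imaging_regions <- unique(flog$region)
  if (!"whole_body" %in% imaging_regions) {
    stop("pipeline requires a whole_body region for remainder-of-body",
         " computation", call. = FALSE)
  }
  organ_regions <- setdiff(imaging_regions, "whole_body")
  mird_sources <- intersect(organ_regions, colnames(S$values))
  dose_targets <- intersect(rownames(S$values), imaging_regions)
  has_lacrimal <- "lacrimal_glands" %in% organ_regions
  blood_av <- unique(ms$patient_id[ms$region == "blood" & ms$cycle == 1L])

  tia_rows <- list()
  dose_rows <- list()
  pk_list <- list()
  blood_tias <- list()

  patients <- unique(flog$patient_id)
  for (pid in patients) {
    pl <- flog[flog$patient_id == pid, ]
    tia1 <- stats::setNames(pl$tia, pl$region)
    rob1 <- remainder_of_body_tia(tia1[["whole_body"]],
                                  tia1[setdiff(names(tia1), "whole_body")])
    conc_tia1 <- NA_real_
    if (pid %in% blood_av) {
      bl <- .blood_conc_tia(ms[ms$patient_id == pid & ms$region == "blood" &
                                 ms$cycle == 1L, ], nuc, policy)
      conc_tia1 <- bl$conc_tia
      blood_tias[[pid]] <- conc_tia1
      pk_list[[pid]] <- tryCatch(
        nca(data.frame(time_h = ms$time_h[ms$patient_id == pid &
                                            ms$region == "blood" &
                                            ms$cycle == 1L],
                       conc = ms$value[ms$patient_id == pid &
                                         ms$region == "blood" &
                                         ms$cycle == 1L])),
        error = function(e) NULL)
    }

    # which cycles does this patient have single-time-point data for?
    pc <- ms[ms$patient_id == pid & ms$region != "blood", ]
    cycles_p <- sort(unique(pc$cycle))
    wb_c1 <- pc[pc$cycle == 1L & pc$region == "whole_body", ]

    for (k in cycles_p) {
      if (k == 1L) {
        tia_k <- tia1
        rob_k <- rob1
        g_marrow <- 1
        sf <- stats::setNames(rep(1, length(tia1)), names(tia1))
      } else {
        sk <- pc[pc$cycle == k, ]
        sf <- numeric(0)
        tia_k <- numeric(0)
        for (rg in sk$region) {
          row_k <- sk[sk$region == rg, ]
          fit1 <- fits[[pid]][[rg]]
          if (is.null(fit1)) {
            stop("missing cycle-1 reference curve for region ", rg,
                 " (patient ", pid, ")", call. = FALSE)
          }
          if (rg == "whole_body") {
            # The whole-body curve is a sum of many compartments, which a
            # low-order fitted curve represents only approximately; the
            # cycle ratio is taken from the measured values at matched
            # nominal times (fitted denominator only when times differ), so
            # proportional kinetics rescale the whole body exactly.
            match_c1 <- wb_c1[abs(wb_c1$time_h - row_k$time_h) < 1e-9, ]
            a_ref <- if (nrow(match_c1) == 1L) match_c1$value
                     else predict_tac(fit1, row_k$time_h)
            sf[rg] <- row_k$value / a_ref
            tia_k[rg] <- tia1[[rg]] * sf[rg]
          } else {
            v <- scale_tia(fit1, tia1[[rg]], row_k$time_h, row_k$value,
                           policy)
            tia_k[rg] <- as.numeric(v)
            sf[rg] <- attr(v, "scale_factor")
          }
        }
        if (!"whole_body" %in% names(tia_k)) {
          stop("cycle ", k, " lacks a whole_body measurement (patient ",
               pid, ")", call. = FALSE)
        }
        rob_k <- remainder_of_body_tia(
          tia_k[["whole_body"]], tia_k[setdiff(names(tia_k), "whole_body")])
        # marrow (blood + remainder-of-body) scales with the whole body
        g_marrow <- sf[["whole_body"]]
      }

      tia_rows[[length(tia_rows) + 1L]] <- data.frame(
        patient_id = pid, cycle = k, region = names(tia_k),
        tia = unname(tia_k), scale_factor = unname(sf[names(tia_k)]),
        stringsAsFactors = FALSE)

      sources <- c(tia_k[mird_sources],
                   remainder_of_body = unname(rob_k))
      organs <- character(0); doses <- numeric(0)
      for (tg in dose_targets) {
        organs <- c(organs, tg)
        doses <- c(doses, organ_dose(sources, S, tg))
      }
      if (has_lacrimal && "lacrimal_glands" %in% names(tia_k)) {
        organs <- c(organs, "lacrimal_glands")
        doses <- c(doses, sphere_self_dose(tia_k[["lacrimal_glands"]],
                                           config$sphere))
      }
      if (!is.na(conc_tia1)) {
        organs <- c(organs, "red_marrow")
        doses <- c(doses, as.numeric(
          red_marrow_dose(conc_tia1 * g_marrow, rob_k, config$marrow)))
      }
      dose_rows[[length(dose_rows) + 1L]] <- data.frame(
        patient_id = pid, cycle = k, organ = organs,
        dose_Gy = unname(doses),
        d_Gy_per_GBq = dose_per_unit_activity(unname(doses), inj_GBq),
        stringsAsFactors = FALSE)
    }
  }

  tia_df <- do.call(rbind, tia_rows)
  doses <- do.call(rbind, dose_rows)

  all_organs <- unique(doses$organ)
  # per-cycle summaries: cycle 1, and cycles 2+ pooled across patient-cycles
  per_cycle <- do.call(rbind, lapply(all_organs, function(og) {
    d1 <- doses$d_Gy_per_GBq[doses$organ == og & doses$cycle == 1L]
    dk <- doses$d_Gy_per_GBq[doses$organ == og & doses$cycle > 1L]
    s1 <- cohort_summary(d1)
    sk <- if (length(dk)) cohort_summary(dk) else NULL
    data.frame(organ = og,
               c1_n = s1$n, c1_mean = s1$mean, c1_sd = s1$sd,
               c1_min = s1$min, c1_max = s1$max,
               ck_n = if (is.null(sk)) 0L else sk$n,
               ck_mean = if (is.null(sk)) NA_real_ else sk$mean,
               ck_sd = if (is.null(sk)) NA_real_ else sk$sd,
               ck_min = if (is.null(sk)) NA_real_ else sk$min,
               ck_max = if (is.null(sk)) NA_real_ else sk$max,
               stringsAsFactors = FALSE)
  }))

  # cumulative records: predicted for every cycle-1 patient, observed for
  # patients with doses in all planned cycles (completers)
  n_by_patient <- stats::aggregate(cycle ~ patient_id, doses,
                                   function(x) length(unique(x)))
  completers <- n_by_patient$patient_id[
    n_by_patient$cycle == config$planned_cycles]
  cum_rows <- list()
  for (pid in patients) {
    dp <- doses[doses$patient_id == pid, ]
    for (og in unique(dp$organ)) {
      d1 <- dp$d_Gy_per_GBq[dp$organ == og & dp$cycle == 1L]
      if (!length(d1)) next
      obs <- if (pid %in% completers) {
        observed_cumulative(dp$dose_Gy[dp$organ == og])
      } else NA_real_
      cum_rows[[length(cum_rows) + 1L]] <- data.frame(
        patient_id = pid, organ = og, d1_Gy_per_GBq = d1,
        predicted_Gy = predict_cumulative(d1, config$planned_total_GBq),
        observed_Gy = obs,
        n_cycles_completed = length(unique(dp$cycle)),
        stringsAsFactors = FALSE)
    }
  }
  cum_records <- do.call(rbind, cum_rows)

  cumulative <- do.call(rbind, lapply(all_organs, function(og) {
    pr <- cum_records$predicted_Gy[cum_records$organ == og]
    ob <- cum_records$observed_Gy[cum_records$organ == og]
    ob <- ob[!is.na(ob)]
    sp <- cohort_summary(pr)
    so <- if (length(ob)) cohort_summary(ob) else NULL
    data.frame(
      organ = og,
      predicted_n = sp$n, predicted_mean = sp$mean, predicted_sd = sp$sd,
      predicted_min = sp$min, predicted_max = sp$max,
      observed_n = if (is.null(so)) 0L else so$n,
      observed_mean = if (is.null(so)) NA_real_ else so$mean,
      observed_sd = if (is.null(so)) NA_real_ else so$sd,
      observed_min = if (is.null(so)) NA_real_ else so$min,
      observed_max = if (is.null(so)) NA_real_ else so$max,
      relative_difference_pct = if (is.null(so) || so$mean <= 0) NA_real_
        else relative_difference(sp$mean, so$mean),
      stringsAsFactors = FALSE)
  }))

  # Hotelling per cycle: predicted-through-k vs observed-through-k on the
  # at-risk organs, over the patients evaluable at cycle k
  at_risk <- intersect(config$at_risk_organs, all_organs)
  hotelling <- list()
  for (k in 2:config$planned_cycles) {
    pk_ids <- n_by_patient$patient_id[n_by_patient$cycle >= k]
    pk_ids <- pk_ids[vapply(pk_ids, function(pid) {
      all(at_risk %in% doses$organ[doses$patient_id == pid &
                                     doses$cycle == 1L])
    }, logical(1))]
    if (length(pk_ids) <= length(at_risk)) next
    pred <- obs <- matrix(NA_real_, length(pk_ids), length(at_risk),
                          dimnames = list(pk_ids, at_risk))
    for (i in seq_along(pk_ids)) {
      dp <- doses[doses$patient_id == pk_ids[i] & doses$cycle <= k, ]
      for (j in seq_along(at_risk)) {
        d1 <- dp$d_Gy_per_GBq[dp$organ == at_risk[j] & dp$cycle == 1L]
        pred[i, j] <- predict_cumulative(d1, inj_GBq * k)
        obs[i, j] <- sum(dp$dose_Gy[dp$organ == at_risk[j]])
      }
    }
    hotelling[[paste0("cycle_", k)]] <- tryCatch(
      hotelling_paired(pred, obs, config$m_comparisons),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "hotelling_error"))
  }

  pk_half <- vapply(pk_list[!vapply(pk_list, is.null, logical(1))],
                    function(x) x$t_half_h, numeric(1))
  pk <- list(
    n = length(pk_half),
    t_half = if (length(pk_half) >= 2L) geometric_summary(pk_half) else NULL,
    per_patient = pk_list
  )

  structure(
    list(fit_log = flog, tia = tia_df, doses = doses,
         per_cycle = per_cycle, cumulative = cumulative,
         cumulative_records = cum_records, completers = completers,
         hotelling = hotelling, pk = pk, config = config,
         phantom = S$phantom_label),
    class = "dosimetry_report"
  )
}

#' @export
print.dosimetry_report <- function(x, digits = 3, ...) {
  cat("Dosimetry report\n")
  cat(sprintf("  patients (cycle 1): %d; completers: %d; phantom: %s\n",
              length(unique(x$fit_log$patient_id)), length(x$completers),
              x$phantom))
  cat(sprintf("  planned activity: %d x %.3g GBq = %.3g GBq\n",
              x$config$planned_cycles, x$config$injected_GBq_per_cycle,
              x$config$planned_total_GBq))
  cat("\nCumulative absorbed doses (Gy), at-risk organs:\n")
  sel <- x$cumulative[x$cumulative$organ %in% x$config$at_risk_organs, ]
  print(format(sel[c("organ", "predicted_mean", "predicted_sd",
                     "observed_mean", "observed_sd",
                     "relative_difference_pct")], digits = digits),
        row.names = FALSE)
  if (!is.null(x$pk$t_half)) {
    cat(sprintf(
      "\nBlood terminal half-life: geometric mean %.3g h (geo CV %.1f%%)\n",
      x$pk$t_half$geomean, x$pk$t_half$geo_cv_percent))
  }
  ps <- vapply(x$hotelling, function(h) {
    if (inherits(h, "hotelling_error")) NA_real_ else h$p_adjusted
  }, numeric(1))
  if (length(ps)) {
    cat(sprintf("Hotelling adjusted p-values (cycles %s): %s\n",
                paste(sub("cycle_", "", names(ps)), collapse = ","),
                paste(signif(ps, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a dosimetry report to JSON
#'
#' Mirrors the per-cycle and cumulative table structure (per-organ mean, SD,
#' min, max, n) plus the Hotelling results and PK summary.
#'
#' @param report A `dosimetry_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "dosimetry_report"))
  hot <- lapply(report$hotelling, function(h) {
    if (inherits(h, "hotelling_error")) list(error = h$error)
    else h[c("t2", "f_stat", "df1", "df2", "p_raw", "p_adjusted", "n")]
  })
  obj <- list(
    planned_total_GBq = report$config$planned_total_GBq,
    per_cycle = report$per_cycle,
    cumulative = report$cumulative,
    hotelling = hot,
    pk = list(n = report$pk$n,
              t_half_geomean_h = report$pk$t_half$geomean,
              t_half_geo_cv_percent = report$pk$t_half$geo_cv_percent)
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
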