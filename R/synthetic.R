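# Synthetic cohorts emulating the dosimetry study design: 30 patients,
# 7.4 GBq per cycle for up to 6 cycles, imaging at {2, 24, 48, 168} h in
# cycle 1 and 48 h in cycles 2-6, 10 blood samples in cycle 1, and the
# observed attrition 29/21/21/19/13/10 evaluable patients per cycle.

#' Study design for a synthetic cohort
#'
#' @param n_patients Number of enrolled patients.
#' @param injected_GBq_per_cycle Administered activity per cycle, GBq.
#' @param cycles Planned number of cycles.
#' @param times_c1 Cycle-1 imaging times, hours.
#' @param time_ck Single imaging time for cycles 2+, hours.
#' @param blood_times_h Blood sampling times (cycle 1), hours; 0 is the
#'   pre-dose draw.
#' @param evaluable_per_cycle Number of dosimetry-evaluable patients per
#'   cycle (non-increasing from cycle 2 on). Patients are evaluable in index
#'   order, so the completers of all cycles are the first
#'   `evaluable_per_cycle[cycles]` patients.
#' @param alt_time_patient,alt_time_cycle,alt_time_h One patient may be
#'   imaged at an alternative time in one later cycle (default: patient 1 at
#'   24 h in cycle 2, mirroring the study); set `alt_time_patient = 0` to
#'   disable.
#' @param seed Integer seed driving all randomness of [generate_cohort()].
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 30L,
                          injected_GBq_per_cycle = 7.4,
                          cycles = 6L,
                          times_c1 = c(2, 24, 48, 168),
                          time_ck = 48,
                          blood_times_h = c(0, 1 / 60, 1 / 3, 1, 2, 4, 24,
                                            48, 72, 144),
                          evaluable_per_cycle = c(29L, 21L, 21L, 19L, 13L, 10L),
                          alt_time_patient = 1L,
                          alt_time_cycle = 2L,
                          alt_time_h = 24,
                          seed = 1L) {
  if (length(evaluable_per_cycle) != cycles) {
    stop("design error: evaluable_per_cycle must have one entry per cycle",
         call. = FALSE)
  }
  if (any(evaluable_per_cycle > n_patients)) {
    stop("design error: evaluable count exceeds n_patients", call. = FALSE)
  }
  if (cycles >= 3L && any(diff(evaluable_per_cycle[-1L]) > 0)) {
    stop("design error: evaluable counts must be non-increasing from cycle 2",
         call. = FALSE)
  }
  if (any(diff(times_c1) <= 0) || any(diff(blood_times_h) <= 0)) {
    stop("design error: sampling times must be strictly increasing",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         injected_GBq_per_cycle = injected_GBq_per_cycle,
         cycles = as.integer(cycles),
         times_c1 = times_c1, time_ck = time_ck,
         blood_times_h = blood_times_h,
         evaluable_per_cycle = as.integer(evaluable_per_cycle),
         alt_time_patient = as.integer(alt_time_patient),
         alt_time_cycle = as.integer(alt_time_cycle),
         alt_time_h = alt_time_h,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# Calibration targets: cycle-1 cohort mean dose per unit activity (Gy/GBq),
# its coefficient of variation, and a physiologic biological washout
# half-life (h) per organ. The uptake amplitudes below are solved so that the
# median patient reproduces the target d given the packaged S fixture.
.default_organ_targets <- function() {
  data.frame(
    organ = c("kidneys", "salivary_glands", "left_colon", "rectum",
              "right_colon", "urinary_bladder_wall", "heart_wall", "lungs",
              "liver", "small_intestine", "spleen", "lacrimal_glands"),
    d_target = c(0.43, 0.63, 0.58, 0.56, 0.32, 0.32, 0.17, 0.11,
                 0.090, 0.071, 0.067, 2.1),
    d_cv = c(0.372, 0.571, 0.241, 0.250, 0.250, 0.094, 0.706, 1.000,
             0.489, 0.437, 0.403, 0.224),
    washout_thalf_h = c(60, 40, 35, 35, 35, 25, 60, 50, 80, 35, 80, 50),
    stringsAsFactors = FALSE
  )
}

#' Kinetic priors for the synthetic cohort
#'
#' Per-organ lognormal priors for uptake amplitude and biological washout
#' half-life, plus the blood-curve prior and noise settings. Median uptake
#' amplitudes are calibrated in closed form so that the median patient's
#' cycle-1 dose per unit activity equals the per-organ calibration targets
#' given the supplied S-value matrix (`f = d * lambda_eff / S_self`; sphere
#' model for the lacrimal glands; the blood biexponential terminal weight is
#' solved so that the median red-marrow dose per unit activity hits its
#' target).
#'
#' @param S An [smatrix()] (default the packaged fixture).
#' @param nuclide A [nuclide()].
#' @param sphere [sphere_params()] used for the lacrimal glands.
#' @param marrow [marrow_params()] used for the red marrow.
#' @param measurement_noise_cv Multiplicative lognormal measurement noise CV
#'   (default 0.10, SPECT-quantification level).
#' @param inter_cycle_cv CV of the lognormal cycle-to-cycle perturbation of
#'   uptake and washout (default 0.20).
#' @param washout_cv Inter-patient CV of biological washout half-lives
#'   (default 0.15).
#' @param organ_targets Data frame `organ`, `d_target`, `d_cv`,
#'   `washout_thalf_h` (defaults emulate the study's per-cycle dose table).
#' @param marrow_d_target Red-marrow dose-per-unit-activity target, Gy/GBq.
#' @param rob_washout_thalf_h Remainder-of-body biological washout, h.
#' @param blood List of blood-curve settings: `volume_mL`, `volume_cv`,
#'   `fast_thalf_h`, `fast_cv`, `terminal_thalf_h`, `terminal_geocv`,
#'   `ka_per_h` (absorption/mixing rate).
#' @return A list of class `kinetic_priors`.
#' @export
kinetic_priors <- function(S = smatrix_lu177(),
                           nuclide = rltdose::nuclide(),
                           sphere = sphere_params(),
                           marrow = marrow_params(),
                           measurement_noise_cv = 0.10,
                           inter_cycle_cv = 0.20,
                           washout_cv = 0.15,
                           organ_targets = .default_organ_targets(),
                           marrow_d_target = 0.035,
                           rob_washout_thalf_h = 30,
                           blood = list(volume_mL = 6000, volume_cv = 0.20,
                                        fast_thalf_h = 1.2, fast_cv = 0.20,
                                        terminal_thalf_h = 41.6,
                                        terminal_geocv = 0.688,
                                        ka_per_h = 8.3)) {
  lp <- nuclide$lambda_phys
  ot <- organ_targets
  ot$lambda_eff_med <- lp + log(2) / ot$washout_thalf_h
  # self S value per organ: matrix diagonal, sphere model for lacrimal glands
  s_self <- numeric(nrow(ot))
  for (i in seq_len(nrow(ot))) {
    org <- ot$organ[i]
    if (org == "lacrimal_glands") {
      s_self[i] <- 1000 * sphere$absorbed_fraction * sphere$delta_local /
        sphere$mass_g
    } else {
      if (!org %in% rownames(S$values) || !org %in% colnames(S$values)) {
        stop("organ missing from S-matrix: ", org, call. = FALSE)
      }
      s_self[i] <- S$values[org, org]
    }
  }
  ot$s_self <- s_self
  # d (Gy/GBq) = f * S_self / lambda_eff  =>  f = d * lambda_eff / S_self
  ot$uptake_med <- ot$d_target * ot$lambda_eff_med / ot$s_self
  sig_w <- sqrt(log(1 + washout_cv^2))
  ot$uptake_sigma <- sqrt(pmax(log(1 + ot$d_cv^2) - sig_w^2, 1e-4))

  # Blood: solve the terminal weight so the median marrow d hits its target.
  lam_z <- log(2) / blood$terminal_thalf_h
  lam_f <- log(2) / blood$fast_thalf_h
  ka <- blood$ka_per_h
  f_rob_med <- max(1 - sum(ot$uptake_med), 0.02)
  lam_rob_med <- lp + log(2) / rob_washout_thalf_h
  rob_tia_per_gbq <- 1000 * f_rob_med / lam_rob_med
  cross_d <- .gy_from_mgy(rob_tia_per_gbq * marrow$s_rm_rob)
  conc_tia_per_gbq <- (marrow_d_target - cross_d) * 1000 /
    (marrow$rmblr * marrow$mass_g / marrow$blood_density_g_per_mL *
       marrow$s_rm_rm)
  if (conc_tia_per_gbq <= 0) {
    stop("marrow calibration infeasible: cross-dose alone exceeds the target",
         call. = FALSE)
  }
  c0_per_gbq <- 1000 / blood$volume_mL
  g_f <- 1 / lam_f - 1 / (lam_f + ka)
  g_z <- 1 / lam_z - 1 / (lam_z + ka)
  w_fast <- (conc_tia_per_gbq / c0_per_gbq - g_z) / (g_f - g_z)
  w_fast <- min(max(w_fast, 0), 1)
  blood$w_fast <- w_fast
  blood$lambda_fast_bio <- max(lam_f - lp, 1e-6)
  blood$lambda_z_bio <- max(lam_z - lp, 1e-6)

  structure(
    list(organs = ot,
         measurement_noise_cv = measurement_noise_cv,
         inter_cycle_cv = inter_cycle_cv,
         washout_cv = washout_cv,
         marrow_d_target = marrow_d_target,
         rob_washout_thalf_h = rob_washout_thalf_h,
         blood = blood,
         sphere = sphere,
         marrow = marrow,
         smatrix = S,
         nuclide = nuclide),
    class = "kinetic_priors"
  )
}

# lognormal multiplier with geometric mean 1 and the given CV
.ln_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic dosimetry cohort
#'
#' Samples per-patient organ kinetics from the priors, builds true
#' time-activity curves (biological washout times physical decay, so every
#' effective half-life is at most the physical one), evaluates them at the
#' design's sampling times with multiplicative lognormal measurement noise,
#' and carries exact ground truth (kinetic parameters, analytic
#' time-integrated activities, and engine-computed absorbed doses per cycle)
#' for parameter-recovery testing. Cycle-to-cycle kinetic variation is a
#' lognormal perturbation of uptake and washout. Patients beyond the
#' evaluable count of a cycle have no measurements for that cycle; dropout
#' follows patient index order, so the run is fully reproducible from the
#' design seed.
#'
#' @param design A [cohort_design()].
#' @param priors A [kinetic_priors()].
#' @param seed Optional override of `design$seed`.
#' @param truth_doses Compute exact per-cycle absorbed doses in the truth
#'   record (default `TRUE`; disable when only the kinetic truth is needed).
#' @return A list of class `synthetic_cohort` with elements `measurements`
#'   (an `activity_measurements` data frame), `truth` (list with `kinetics`,
#'   `blood`, `doses` data frames), `design`, `priors`.
#' @export
generate_cohort <- function(design = cohort_design(),
                            priors = kinetic_priors(),
                            seed = NULL, truth_doses = TRUE) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(priors, "kinetic_priors"))
  seed <- if (is.null(seed)) design$seed else as.integer(seed)
  .with_seed(seed, .generate_cohort_impl(design, priors, truth_doses))
}

.generate_cohort_impl <- function(design, priors, truth_doses = TRUE) {
  nuc <- priors$nuclide
  lp <- nuc$lambda_phys
  inj_MBq <- design$injected_GBq_per_cycle * 1000
  np <- design$n_patients
  ids <- sprintf("P%02d", seq_len(np))
  ot <- priors$organs
  norg <- nrow(ot)
  sig_w <- sqrt(log(1 + priors$washout_cv^2))

  # patient-level kinetic parameters (cycle-1 baseline)
  f1 <- matrix(0, np, norg, dimnames = list(ids, ot$organ))
  lam_bio1 <- matrix(0, np, norg, dimnames = list(ids, ot$organ))
  for (j in seq_len(norg)) {
    f1[, j] <- ot$uptake_med[j] * exp(stats::rnorm(np, 0, ot$uptake_sigma[j]))
    lam_bio1[, j] <- (log(2) / ot$washout_thalf_h[j]) *
      exp(stats::rnorm(np, 0, sig_w))
  }
  f_rob1 <- pmax(1 - rowSums(f1), 0.02)
  lam_rob_bio1 <- (log(2) / priors$rob_washout_thalf_h) *
    exp(stats::rnorm(np, 0, sig_w))

  bl <- priors$blood
  blood_c0 <- inj_MBq / (bl$volume_mL * .ln_mult(np, bl$volume_cv))
  blood_lf <- pmax((log(2) / bl$fast_thalf_h) * .ln_mult(np, bl$fast_cv), lp)
  # terminal half-life lognormal around its geometric-mean target, clamped
  # so no effective half-life exceeds the physical one
  sig_z <- sqrt(log(1 + bl$terminal_geocv^2))
  blood_lz <- pmax((log(2) / bl$terminal_thalf_h) *
                     exp(stats::rnorm(np, 0, sig_z)), lp)
  ka <- bl$ka_per_h
  w <- bl$w_fast

  # per cycle multiplicative perturbations (cycle 1 = 1)
  cyc_f <- array(1, c(np, norg + 1L, design$cycles))
  cyc_l <- array(1, c(np, norg + 1L, design$cycles))
  if (design$cycles > 1L && priors$inter_cycle_cv > 0) {
    nrep <- np * (norg + 1L) * (design$cycles - 1L)
    cyc_f[, , -1L] <- .ln_mult(nrep, priors$inter_cycle_cv)
    cyc_l[, , -1L] <- .ln_mult(nrep, priors$inter_cycle_cv)
  }

  sig_n <- sqrt(log(1 + priors$measurement_noise_cv^2))
  noise <- function(n) if (sig_n > 0) exp(stats::rnorm(n, 0, sig_n)) else rep(1, n)

  kin <- list(); meas <- list(); blood_rows <- list(); ki <- 0L
  blood_truth <- data.frame(patient_id = ids, c0 = blood_c0, w_fast = w,
                            lambda_fast = blood_lf, lambda_z = blood_lz,
                            ka = ka,
                            conc_tia = blood_c0 *
                              (w * (1 / blood_lf - 1 / (blood_lf + ka)) +
                               (1 - w) * (1 / blood_lz - 1 / (blood_lz + ka))),
                            stringsAsFactors = FALSE)

  blood_curve <- function(i, t) {
    ifelse(t <= 0, 0,
           blood_c0[i] * (w * exp(-blood_lf[i] * t) +
                          (1 - w) * exp(-blood_lz[i] * t)) *
             (1 - exp(-ka * t)))
  }

  for (k in seq_len(design$cycles)) {
    ev <- seq_len(design$evaluable_per_cycle[k])
    tk <- if (k == 1L) design$times_c1 else design$time_ck
    for (i in ev) {
      t_i <- tk
      if (k > 1L && i == design$alt_time_patient &&
          k == design$alt_time_cycle) {
        t_i <- design$alt_time_h
      }
      amp <- inj_MBq * f1[i, ] * cyc_f[i, seq_len(norg), k]
      lam <- lp + lam_bio1[i, ] * cyc_l[i, seq_len(norg), k]
      amp_rob <- inj_MBq * f_rob1[i] * cyc_f[i, norg + 1L, k]
      lam_rob <- lp + lam_rob_bio1[i] * cyc_l[i, norg + 1L, k]

      ki <- ki + 1L
      kin[[ki]] <- data.frame(
        patient_id = ids[i], cycle = k,
        region = c(ot$organ, "remainder_of_body", "whole_body"),
        amplitude_MBq = c(amp, amp_rob, NA_real_),
        lambda_eff = c(lam, lam_rob, NA_real_),
        tia = c(amp / lam, amp_rob / lam_rob,
                sum(amp / lam) + amp_rob / lam_rob),
        stringsAsFactors = FALSE
      )

      organ_vals <- vapply(
        t_i, function(tt) sum(amp * exp(-lam * tt)) + amp_rob *
          exp(-lam_rob * tt), numeric(1))
      a_mat <- outer(amp, t_i, function(a, tt) a) *
        exp(-outer(lam, t_i))
      n_meas <- length(t_i) * (norg + 1L)
      meas[[length(meas) + 1L]] <- data.frame(
        patient_id = ids[i], cycle = k,
        region = rep(c(ot$organ, "whole_body"), each = length(t_i)),
        time_h = rep(t_i, norg + 1L),
        value = c(t(a_mat), organ_vals) * noise(n_meas),
        unit = "MBq", stringsAsFactors = FALSE
      )
      if (k == 1L) {
        bt <- design$blood_times_h
        cv <- blood_curve(i, bt)
        nz <- cv > 0
        cv[nz] <- cv[nz] * noise(sum(nz))
        blood_rows[[length(blood_rows) + 1L]] <- data.frame(
          patient_id = ids[i], cycle = 1L, region = "blood",
          time_h = bt, value = cv, unit = "MBq_per_mL",
          stringsAsFactors = FALSE
        )
      }
    }
  }

  kinetics <- do.call(rbind, kin)
  measurements <- validate_measurements(
    do.call(rbind, c(meas, blood_rows)))

  doses <- if (truth_doses) {
    .truth_doses(kinetics, blood_truth, design, priors)
  } else NULL

  structure(
    list(measurements = measurements,
         truth = list(kinetics = kinetics, blood = blood_truth,
                      doses = doses),
         design = design, priors = priors),
    class = "synthetic_cohort"
  )
}

# Exact absorbed doses per patient/cycle/organ from the ground-truth TIAs.
# The MIRD sum is evaluated as one matrix product over all patient-cycles;
# a unit test pins it against per-target organ_dose() calls. Blood (and
# hence marrow self-dose) varies across cycles with the remainder-of-body
# amplitude factor, reflecting that circulating and unbound activity move
# together.
.truth_doses <- function(kinetics, blood_truth, design, priors) {
  S <- priors$smatrix
  organs_s <- intersect(priors$organs$organ, colnames(S$values))
  sources <- c(organs_s, "remainder_of_body")
  inj_GBq <- design$injected_GBq_per_cycle
  key <- paste(kinetics$patient_id, kinetics$cycle, sep = "\r")
  ukey <- unique(key)
  # TIA matrix: one row per patient-cycle, one column per source organ
  tia_mat <- matrix(0, length(ukey), length(sources),
                    dimnames = list(ukey, sources))
  for (src in sources) {
    rows <- kinetics$region == src
    tia_mat[match(key[rows], ukey), src] <- kinetics$tia[rows]
  }
  lac_tia <- numeric(length(ukey))
  rows <- kinetics$region == "lacrimal_glands"
  lac_tia[match(key[rows], ukey)] <- kinetics$tia[rows]

  dose_s <- tia_mat %*% t(S$values[organs_s, sources, drop = FALSE]) / 1000
  lac <- sphere_self_dose(lac_tia, priors$sphere)

  pid_u <- sub("\r.*", "", ukey)
  cyc_u <- as.integer(sub(".*\r", "", ukey))
  rob <- tia_mat[, "remainder_of_body"]
  rob1 <- rob[match(paste(pid_u, 1L, sep = "\r"), ukey)]
  conc_tia <- blood_truth$conc_tia[match(pid_u, blood_truth$patient_id)] *
    rob / rob1
  mp <- priors$marrow
  rm_dose <- .gy_from_mgy(
    mp$rmblr * conc_tia * mp$mass_g / mp$blood_density_g_per_mL *
      mp$s_rm_rm + rob * mp$s_rm_rob)

  all_dose <- cbind(dose_s, lacrimal_glands = lac, red_marrow = rm_dose)
  organ_names <- colnames(all_dose)
  data.frame(
    patient_id = rep(pid_u, each = length(organ_names)),
    cycle = rep(cyc_u, each = length(organ_names)),
    organ = rep(organ_names, times = length(ukey)),
    dose_Gy = as.vector(t(all_dose)),
    d_Gy_per_GBq = as.vector(t(all_dose)) / inj_GBq,
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d patients, %d cycles, %d measurements (seed %d)\n",
    x$design$n_patients, x$design$cycles, nrow(x$measurements),
    x$design$seed))
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares pipeline estimates with the generator's ground truth and reports
#' relative bias and RMSE (percent) per region and overall, for each metric
#' column the two frames share (`tia`, `dose_Gy`, `t_eff_h`).
#'
#' @param truth Data frame with `patient_id`, `region` and metric columns
#'   (e.g. `truth$kinetics` of a [generate_cohort()] result restricted to
#'   one cycle, with `t_eff_h = log(2) / lambda_eff`).
#' @param estimates Data frame with the same key and metric columns.
#' @return Data frame with one row per region (plus `"overall"`) and, per
#'   metric, `<metric>_bias_pct` (mean relative error) and
#'   `<metric>_rmse_pct`.
#' @export
recovery_report <- function(truth, estimates) {
  keys <- c("patient_id", "region")
  if (!all(keys %in% names(truth)) || !all(keys %in% names(estimates))) {
    stop("both frames need patient_id and region columns", call. = FALSE)
  }
  metrics <- setdiff(intersect(names(truth), names(estimates)), c(keys, "cycle"))
  metrics <- metrics[vapply(metrics, function(m) is.numeric(truth[[m]]),
                            logical(1))]
  if (!length(metrics)) stop("no shared metric columns", call. = FALSE)
  m <- merge(truth[c(keys, metrics)], estimates[c(keys, metrics)],
             by = keys, suffixes = c("_true", "_est"))
  if (nrow(m) != nrow(estimates)) {
    stop("alignment error: estimate keys not all present in truth",
         call. = FALSE)
  }
  regions <- c(sort(unique(m$region)), "overall")
  rows <- lapply(regions, function(rg) {
    sub <- if (rg == "overall") m else m[m$region == rg, ]
    row <- list(region = rg, n = nrow(sub))
    for (met in metrics) {
      rel <- (sub[[paste0(met, "_est")]] - sub[[paste0(met, "_true")]]) /
        sub[[paste0(met, "_true")]]
      row[[paste0(met, "_bias_pct")]] <- 100 * mean(rel)
      row[[paste0(met, "_rmse_pct")]] <- 100 * sqrt(mean(rel^2))
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
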