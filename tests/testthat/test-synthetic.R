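test_that("cohort generation is reproducible and honors the design", {
  pr <- kinetic_priors()
  co1 <- generate_cohort(cohort_design(seed = 5), pr)
  co2 <- generate_cohort(cohort_design(seed = 5), pr)
  expect_identical(co1$measurements, co2$measurements)
  expect_identical(co1$truth$kinetics, co2$truth$kinetics)
  co3 <- generate_cohort(cohort_design(seed = 6), pr)
  expect_false(identical(co1$measurements$value, co3$measurements$value))

  # evaluable counts per cycle and nested dropout
  ms <- co1$measurements
  des <- co1$design
  for (k in seq_len(des$cycles)) {
    ids <- unique(ms$patient_id[ms$cycle == k & ms$region != "blood"])
    expect_length(ids, des$evaluable_per_cycle[k])
  }
  # completers are a subset of every earlier cycle's evaluable set
  comp <- unique(ms$patient_id[ms$cycle == des$cycles])
  for (k in 2:des$cycles) {
    expect_true(all(comp %in% ms$patient_id[ms$cycle == k]))
  }
  # cycle-1 imaging regions have 4 time points, later cycles exactly 1
  n1 <- table(ms$region[ms$cycle == 1 & ms$patient_id == "P02" &
                          ms$region != "blood"])
  expect_true(all(n1 == 4))
  nk <- table(ms$region[ms$cycle == 3 & ms$patient_id == "P02"])
  expect_true(all(nk == 1))
  # the alternative-time patient is imaged at 24 h in cycle 2
  t_alt <- unique(ms$time_h[ms$cycle == 2 & ms$patient_id == "P01"])
  expect_identical(t_alt, 24)
})

test_that("invalid designs are rejected", {
  expect_error(cohort_design(n_patients = 10,
                             evaluable_per_cycle = c(11, 9, 8, 7, 6, 5)),
               "design error")
  expect_error(cohort_design(evaluable_per_cycle = c(29, 10, 21, 19, 13, 10)),
               "design error")
  expect_error(cohort_design(times_c1 = c(2, 2, 48, 168)), "design error")
  expect_error(cohort_design(evaluable_per_cycle = c(29, 21, 21)),
               "one entry per cycle")
})

test_that("noiseless measurements lie exactly on the true curves", {
  co <- generate_cohort(small_design(seed = 2), quiet_priors())
  ms <- co$measurements
  kin <- co$truth$kinetics
  for (pid in c("P01", "P05")) {
    for (rg in c("kidneys", "liver", "lacrimal_glands")) {
      k1 <- kin[kin$patient_id == pid & kin$cycle == 1 & kin$region == rg, ]
      m1 <- ms[ms$patient_id == pid & ms$cycle == 1 & ms$region == rg, ]
      expect_equal(m1$value,
                   k1$amplitude_MBq * exp(-k1$lambda_eff * m1$time_h),
                   tolerance = 1e-12)
    }
    # whole body is the sum of organ and remainder compartments
    k1 <- kin[kin$patient_id == pid & kin$cycle == 1 &
                !kin$region %in% "whole_body", ]
    m1 <- ms[ms$patient_id == pid & ms$cycle == 1 &
               ms$region == "whole_body", ]
    wb <- vapply(m1$time_h, function(tt) {
      sum(k1$amplitude_MBq * exp(-k1$lambda_eff * tt))
    }, numeric(1))
    expect_equal(m1$value, wb, tolerance = 1e-12)
  }
  # truth whole-body TIA equals the compartment sum
  kwb <- kin[kin$region == "whole_body" & kin$cycle == 1, ]
  ksum <- stats::aggregate(
    tia ~ patient_id, kin[kin$cycle == 1 & kin$region != "whole_body", ], sum)
  expect_equal(kwb$tia[order(kwb$patient_id)],
               ksum$tia[order(ksum$patient_id)], tolerance = 1e-12)
})

test_that("every sampled effective half-life respects the physical limit", {
  co <- generate_cohort(cohort_design(seed = 9))
  kin <- co$truth$kinetics
  lam <- kin$lambda_eff[!is.na(kin$lambda_eff)]
  expect_true(all(lam >= nuclide()$lambda_phys))
})

test_that("truth doses agree with the dose engine route", {
  pr <- kinetic_priors()
  co <- generate_cohort(small_design(seed = 4), pr)
  S <- pr$smatrix
  organs_s <- intersect(pr$organs$organ, colnames(S$values))
  kin <- co$truth$kinetics
  for (key in list(c("P02", 1), c("P03", 2))) {
    kk <- kin[kin$patient_id == key[1] & kin$cycle == as.integer(key[2]), ]
    tia_by <- stats::setNames(kk$tia, kk$region)
    src <- c(tia_by[organs_s],
             remainder_of_body = unname(tia_by["remainder_of_body"]))
    for (tg in c("kidneys", "liver", "rectum")) {
      ref <- organ_dose(src, S, tg)
      got <- co$truth$doses$dose_Gy[
        co$truth$doses$patient_id == key[1] &
          co$truth$doses$cycle == as.integer(key[2]) &
          co$truth$doses$organ == tg]
      expect_equal(got, ref, tolerance = 1e-12)
    }
    lac_ref <- sphere_self_dose(tia_by[["lacrimal_glands"]], pr$sphere)
    lac_got <- co$truth$doses$dose_Gy[
      co$truth$doses$patient_id == key[1] &
        co$truth$doses$cycle == as.integer(key[2]) &
        co$truth$doses$organ == "lacrimal_glands"]
    expect_equal(lac_got, lac_ref, tolerance = 1e-12)
  }
})

test_that("recovery reports quantify bias exactly in constructed cases", {
  truth <- data.frame(patient_id = rep(c("A", "B"), each = 2),
                      region = rep(c("kidneys", "liver"), 2),
                      tia = c(100, 50, 200, 80),
                      stringsAsFactors = FALSE)
  est <- truth
  r0 <- recovery_report(truth, est)
  expect_true(all(abs(r0$tia_bias_pct) < 1e-12))
  expect_true(all(abs(r0$tia_rmse_pct) < 1e-12))
  est$tia <- truth$tia * 1.1
  r1 <- recovery_report(truth, est)
  expect_equal(r1$tia_bias_pct, rep(10, nrow(r1)), tolerance = 1e-10)
  expect_equal(r1$tia_rmse_pct, rep(10, nrow(r1)), tolerance = 1e-10)
  est_bad <- est
  est_bad$patient_id[1] <- "Z"
  expect_error(recovery_report(truth, est_bad), "alignment error")
})

test_that("default priors keep the cohort mean kidney dose near its target", {
  # simulation oracle over repeated cohorts: grand mean within +/-30% of
  # 0.43 Gy/GBq (the lognormal mean-median shift is ~+10%)
  pr <- kinetic_priors()
  means <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_design(seed = 20000 + s), pr)
    d <- co$truth$doses
    mean(d$d_Gy_per_GBq[d$cycle == 1 & d$organ == "kidneys"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.43) / 0.43, 0.30)
})
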