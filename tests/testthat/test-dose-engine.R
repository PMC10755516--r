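test_that("the MIRD sum is correct, additive and linear", {
  S1 <- smatrix(matrix(1, 1, 1, dimnames = list("kidneys", "kidneys")))
  expect_equal(organ_dose(c(kidneys = 1000), S1, "kidneys"), 1.0)

  S2 <- smatrix(matrix(c(0.5, 0.5), 1, 2,
                       dimnames = list("kidneys", c("kidneys", "liver"))))
  expect_equal(organ_dose(c(kidneys = 500, liver = 500), S2, "kidneys"),
               organ_dose(c(kidneys = 1000), S1, "kidneys") / 2)

  # brute-force oracle on random 5x5 matrices
  orgs <- paste0("o", 1:5)
  for (s in 1:20) {
    set.seed(s)
    m <- matrix(runif(25, 0, 2), 5, 5, dimnames = list(orgs, orgs))
    S <- smatrix(m)
    tias <- stats::setNames(runif(5, 0, 5000), orgs)
    for (tg in orgs) {
      brute <- 0
      for (src in orgs) brute <- brute + tias[[src]] * m[tg, src]
      expect_equal(organ_dose(tias, S, tg), brute / 1000, tolerance = 1e-12)
    }
    # linearity in the TIA vector
    expect_equal(organ_dose(tias * 3.7, S, "o1"),
                 3.7 * organ_dose(tias, S, "o1"), tolerance = 1e-12)
  }
})

test_that("unknown labels and invalid TIAs are rejected", {
  S <- smatrix(matrix(1, 1, 1, dimnames = list("kidneys", "kidneys")))
  expect_error(organ_dose(c(kidneys = 1), S, "liver"), "unknown target")
  expect_error(organ_dose(c(liver = 1), S, "kidneys"), "unknown source")
  expect_error(organ_dose(c(kidneys = -1), S, "kidneys"), "invalid input")
})

test_that("dose per unit activity is a simple validated ratio", {
  expect_equal(dose_per_unit_activity(3.182, 7.4), 0.43, tolerance = 1e-12)
  expect_identical(dose_per_unit_activity(0, 7.4), 0)
  expect_identical(dose_per_unit_activity(7.4, 7.4), 1)
  expect_error(dose_per_unit_activity(1, 0), "invalid activity")
})

test_that("sphere self-dose follows the energy bookkeeping", {
  expect_identical(sphere_self_dose(0), 0)
  p1 <- sphere_params(mass_g = 1, absorbed_fraction = 1)
  p2 <- sphere_params(mass_g = 2, absorbed_fraction = 1)
  expect_equal(sphere_self_dose(1000, p1), 2 * sphere_self_dose(1000, p2))

  # independent oracle: energy per decay x decays per MBq.h / mass
  e_joule <- 147.9e3 * 1.602176634e-19
  decays <- 3.6e9 * 1000        # 1000 MBq.h
  dose_gy <- e_joule * decays / 0.001 # 1 g = 1e-3 kg
  expect_equal(sphere_self_dose(1000, p1), dose_gy, tolerance = 1e-9)
  expect_error(sphere_params(mass_g = 0), "invalid parameter")
  expect_error(sphere_params(absorbed_fraction = 1.2), "invalid parameter")
})

test_that("blood-based marrow dose matches the two-term hand computation", {
  p <- marrow_params(rmblr = 1, mass_g = 1100, s_rm_rm = 0.02,
                     s_rm_rob = 0.001)
  d <- red_marrow_dose(2, 50000, p)
  expect_equal(as.numeric(d), (2 * 1100 * 0.02 + 50000 * 0.001) / 1000)
  comp <- attr(d, "components")
  expect_equal(unname(comp["self"] + comp["cross"]), as.numeric(d))

  # no blood activity -> cross-dose only; rmblr = 0 is equivalent
  cross_only <- red_marrow_dose(0, 50000, p)
  expect_equal(as.numeric(cross_only), 50000 * 0.001 / 1000)
  p0 <- marrow_params(rmblr = 0, mass_g = 1100, s_rm_rm = 0.02,
                      s_rm_rob = 0.001)
  expect_equal(as.numeric(red_marrow_dose(2, 50000, p0)),
               as.numeric(cross_only))
  expect_error(red_marrow_dose(-1, 0, p), "invalid input")
})

test_that("remainder of body is whole body minus the modelled organs", {
  expect_equal(remainder_of_body_tia(10000, c(4000, 3000)), 3000)
  expect_equal(remainder_of_body_tia(10000), 10000)
  expect_error(remainder_of_body_tia(10000, c(8000, 3000)), "inconsistency")
  # within tolerance, clipped at zero
  expect_equal(remainder_of_body_tia(1, c(0.5, 0.5 + 1e-9)), 0)
})

test_that("S-matrix CSV round trip preserves labels and values", {
  orgs <- c("kidneys", "liver")
  m <- matrix(c(0.29, 2e-4, 1e-3, 0.05), 2, 2,
              dimnames = list(orgs, orgs))
  S <- smatrix(m, phantom_label = "toy")
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_smatrix(S, path)
  S2 <- read_smatrix(path)
  expect_equal(S2$values, S$values, tolerance = 1e-12)
})

test_that("the packaged synthetic S fixture is well formed", {
  S <- smatrix_lu177()
  expect_true(all(S$values >= 0))
  expect_true(all(c("kidneys", "liver", "salivary_glands") %in%
                    rownames(S$values)))
  expect_true("remainder_of_body" %in% colnames(S$values))
  # self-dose dominates cross-dose for every organ present in both axes
  shared <- intersect(rownames(S$values), colnames(S$values))
  for (og in shared) {
    expect_gt(S$values[og, og], max(S$values[og, setdiff(shared, og)]))
  }
})
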