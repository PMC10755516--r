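# Shared fixtures: all test data is generated in code.

lu <- nuclide()

# noiseless activity table for one region
mono_df <- function(t, a0, lambda, region = "kidneys", cycle = 1L) {
  data.frame(patient_id = "P01", cycle = cycle, region = region,
             time_h = t, value = a0 * exp(-lambda * t), unit = "MBq",
             stringsAsFactors = FALSE)
}

# construct a tac_fit directly (for closed-form integrator tests)
make_fit <- function(amplitude, rate, region = "organ") {
  structure(
    list(region = region,
         model = if (length(rate) == 1L) "mono" else "biexp",
         terms = data.frame(amplitude = amplitude, rate = rate),
         fit_quality = 0, n_points = 4L,
         lambda_phys = lu$lambda_phys, clamped = FALSE),
    class = "tac_fit"
  )
}

# small fast cohort (fewer patients/cycles) for pipeline tests
small_design <- function(seed = 1L) {
  cohort_design(n_patients = 8L, cycles = 3L,
                evaluable_per_cycle = c(8L, 6L, 4L),
                alt_time_patient = 1L, alt_time_cycle = 2L, alt_time_h = 24,
                seed = seed)
}

quiet_priors <- function(...) {
  kinetic_priors(measurement_noise_cv = 0, inter_cycle_cv = 0, ...)
}
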