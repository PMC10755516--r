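#' Radionuclide decay data
#'
#' Holds the physical half-life and decay constant of the therapeutic nuclide.
#' The default is Lu-177 with the ICRP 107 half-life of 6.647 days.
#'
#' @param name Nuclide label.
#' @param half_life_h Physical half-life in hours (> 0).
#'
#' @return An object of class `nuclide_data` with fields `name`,
#'   `half_life_h` and `lambda_phys` (1/h), where
#'   `lambda_phys = log(2) / half_life_h`.
#' @examples
#' lu <- nuclide()
#' lu$lambda_phys * lu$half_life_h # log(2)
#' @export
nuclide <- function(name = "Lu-177", half_life_h = 6.647 * 24) {
  if (!is.numeric(half_life_h) || length(half_life_h) != 1L ||
      !is.finite(half_life_h) || half_life_h <= 0) {
    stop("`half_life_h` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name)[1L],
      half_life_h = half_life_h,
      lambda_phys = log(2) / half_life_h
    ),
    class = "nuclide_data"
  )
}

#' @export
print.nuclide_data <- function(x, ...) {
  cat(sprintf(
    "<nuclide_data> %s: T1/2 = %.4g h (%.4g d), lambda = %.6g /h\n",
    x$name, x$half_life_h, x$half_life_h / 24, x$lambda_phys
  ))
  invisible(x)
}

# Lu-177 emission bookkeeping used by the synthetic S-value fixture and the
# sphere-model defaults. Energies are per decay; the non-penetrating value
# bundles the mean beta energy with conversion/Auger electrons.

#' Mean Lu-177 non-penetrating (electron) energy per decay, keV
#' @export
LU177_NONPENETRATING_KEV <- 147.9

#' Mean Lu-177 photon energy per decay, keV
#' @export
LU177_PHOTON_KEV <- 31.0

#' Equilibrium dose constant from mean emitted energy per decay
#'
#' Converts a mean emitted energy per decay (keV) into an equilibrium dose
#' constant in Gy.g/(MBq.h): `keV * 1.602176634e-16 J/keV * 3.6e9 decays per
#' MBq.h * 1000 g/kg`.
#'
#' @param energy_kev Mean energy emitted per decay, keV.
#' @return Equilibrium dose constant, Gy.g/(MBq.h).
#' @examples
#' delta_constant(LU177_NONPENETRATING_KEV) # ~0.0853 for Lu-177 electrons
#' @export
delta_constant <- function(energy_kev) {
  stopifnot(is.numeric(energy_kev), all(energy_kev >= 0))
  energy_kev * 1.602176634e-16 * 3.6e9 * 1000
}

# Single place where the S-value unit convention (mGy per MBq.h) is turned
# into Gy. All dose outputs in the package are Gy.
.gy_from_mgy <- function(x) x / 1000
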