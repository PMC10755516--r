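#' Normalize organ/region labels to the controlled vocabulary
#'
#' Region labels are normalized to snake_case at parse time so that organ
#' names coming from different sites ("Urinary bladder wall", "urinary-bladder
#' wall") map onto a single vocabulary. A small alias map handles spellings
#' that do not normalize mechanically.
#'
#' @param x Character vector of region labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_region(c("Urinary bladder wall", "Red Marrow", "whole body"))
#' @export
normalize_region <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[^a-z0-9]+", "_", out)
  out <- gsub("^_+|_+$", "", out)
  aliases <- c(
    bladder_wall = "urinary_bladder_wall",
    bladder = "urinary_bladder_wall",
    marrow = "red_marrow",
    bone_marrow = "red_marrow",
    total_body = "whole_body",
    wholebody = "whole_body",
    lacrimal = "lacrimal_glands",
    lacrimal_gland = "lacrimal_glands",
    salivary = "salivary_glands",
    salivary_gland = "salivary_glands",
    kidney = "kidneys",
    lung = "lungs"
  )
  hit <- out %in% names(aliases)
  out[hit] <- unname(aliases[out[hit]])
  out
}

MEASUREMENT_COLUMNS <- c("patient_id", "cycle", "region", "time_h", "value", "unit")

#' Read activity measurements from CSV
#'
#' The measurements file is the pipeline's raw input: one row per quantified
#' activity for one patient/cycle/region/time. Required columns are
#' `patient_id`, `cycle`, `region`, `time_h`, `value`, `unit`, with
#' `unit` either `"MBq"` (organ/whole-body activity) or `"MBq_per_mL"`
#' (blood activity concentration).
#'
#' @param path Path to a UTF-8 CSV file with a header.
#' @return A `data.frame` of class `activity_measurements` with normalized
#'   region labels and a `row` column retaining source row numbers for error
#'   reporting.
#' @seealso [write_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop("measurements file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing)) {
    stop("measurements file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[MEASUREMENT_COLUMNS]
  df$row <- seq_len(nrow(df)) + 1L  # +1: header line
  validate_measurements(df)
}

#' Validate a measurements data frame
#'
#' Applies the same checks as [read_measurements()] to an in-memory data
#' frame (types, units, non-negative activity, finite times, duplicate
#' time points).
#'
#' @param df Data frame with the measurement columns.
#' @return The validated data frame with class `activity_measurements`.
#' @export
validate_measurements <- function(df) {
  if (is.null(df$row)) df$row <- seq_len(nrow(df))
  df$patient_id <- as.character(df$patient_id)
  df$region <- normalize_region(df$region)
  for (col in c("cycle", "time_h", "value")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric or non-finite `%s` at row(s) %s", col,
                   paste(df$row[bad], collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$cycle <- as.integer(df$cycle)
  if (any(df$cycle < 1L | df$cycle > 6L)) {
    bad <- df$row[df$cycle < 1L | df$cycle > 6L]
    stop("cycle out of range 1-6 at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$time_h < 0)) {
    stop("negative time_h at row(s) ",
         paste(df$row[df$time_h < 0], collapse = ", "), call. = FALSE)
  }
  if (any(df$value < 0)) {
    stop("negative activity at row(s) ",
         paste(df$row[df$value < 0], collapse = ", "), call. = FALSE)
  }
  if (!all(df$unit %in% c("MBq", "MBq_per_mL"))) {
    bad <- df$row[!df$unit %in% c("MBq", "MBq_per_mL")]
    stop("unknown unit (expected MBq or MBq_per_mL) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$patient_id, df$cycle, df$region, df$time_h, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate (patient, cycle, region, time) measurement at row(s) ",
         paste(df$row[dup], collapse = ", "), call. = FALSE)
  }
  class(df) <- c("activity_measurements", "data.frame")
  df
}

#' Write activity measurements to CSV
#'
#' @param df A measurements data frame (see [read_measurements()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  utils::write.csv(as.data.frame(df)[MEASUREMENT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the study design constants and analysis options used by
#' [run_pipeline()]. The planned total activity is always
#' `planned_cycles * injected_GBq_per_cycle` (44.4 GBq at the defaults).
#'
#' @param nuclide A [nuclide()] object.
#' @param injected_GBq_per_cycle Administered activity per cycle, GBq.
#' @param planned_cycles Planned number of cycles.
#' @param at_risk_organs Organs entering the multivariate predicted-vs-observed
#'   comparison.
#' @param tia_mode Integration mode for time-integrated activity, `"analytic"`
#'   (integral of the fitted curve; default) or `"hybrid"` (trapezoid over the
#'   observed range plus analytic tail).
#' @param sphere [sphere_params()] for lacrimal-gland self-dose.
#' @param marrow [marrow_params()] for blood-based red-marrow dose.
#' @param m_comparisons Bonferroni family size for the Hotelling tests.
#' @param tac_policy Curve-fit policy, see [tac_policy()].
#' @param seed Optional integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(nuclide = rltdose::nuclide(),
                       injected_GBq_per_cycle = 7.4,
                       planned_cycles = 6L,
                       at_risk_organs = c("kidneys", "lacrimal_glands",
                                          "salivary_glands", "red_marrow"),
                       tia_mode = c("analytic", "hybrid"),
                       sphere = sphere_params(),
                       marrow = marrow_params(),
                       m_comparisons = 5L,
                       tac_policy = rltdose::tac_policy(),
                       seed = NULL) {
  stopifnot(inherits(nuclide, "nuclide_data"),
            injected_GBq_per_cycle > 0, planned_cycles >= 1)
  tia_mode <- match.arg(tia_mode)
  structure(
    list(
      nuclide = nuclide,
      injected_GBq_per_cycle = injected_GBq_per_cycle,
      planned_cycles = as.integer(planned_cycles),
      planned_total_GBq = planned_cycles * injected_GBq_per_cycle,
      at_risk_organs = normalize_region(at_risk_organs),
      tia_mode = tia_mode,
      sphere = sphere,
      marrow = marrow,
      m_comparisons = as.integer(m_comparisons),
      tac_policy = tac_policy,
      seed = seed
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognized keys (all optional, defaults from [run_config()]):
#' `nuclide: {name, half_life_h}`, `injected_GBq_per_cycle`, `planned_cycles`,
#' `at_risk_organs`, `tia_mode`, `sphere: {mass_g, absorbed_fraction}`,
#' `marrow: {rmblr, mass_g}`, `m_comparisons`, `seed`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nuc <- if (!is.null(cfg$nuclide)) {
    nuclide(name = cfg$nuclide$name %||% "Lu-177",
            half_life_h = cfg$nuclide$half_life_h %||% (6.647 * 24))
  } else {
    nuclide()
  }
  sp <- do.call(sphere_params, as.list(cfg$sphere %||% list()))
  mp <- do.call(marrow_params, as.list(cfg$marrow %||% list()))
  run_config(
    nuclide = nuc,
    injected_GBq_per_cycle = cfg$injected_GBq_per_cycle %||% 7.4,
    planned_cycles = cfg$planned_cycles %||% 6L,
    at_risk_organs = cfg$at_risk_organs %||%
      c("kidneys", "lacrimal_glands", "salivary_glands", "red_marrow"),
    tia_mode = cfg$tia_mode %||% "analytic",
    sphere = sp,
    marrow = mp,
    m_comparisons = cfg$m_comparisons %||% 5L,
    seed = cfg$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
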