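# Subject exercise-test records: data model, CSV I/O, packaged fixtures and
# the brachial -> aortic -> ventricular pressure-transform chain.

SUBJECT_COLUMNS <- c(
  "subject_id", "heart_rate_bpm", "brachial_sys_mmHg", "brachial_dia_mmHg",
  "aortic_sys_mmHg", "aortic_dia_mmHg", "ventricular_sys_mmHg",
  "doppler_co_ml_min", "numerical_co_ml_min", "ejection_time_s"
)
MANDATORY_COLUMNS <- c(
  "subject_id", "heart_rate_bpm", "aortic_sys_mmHg", "aortic_dia_mmHg",
  "ventricular_sys_mmHg", "doppler_co_ml_min"
)

#' Construct a subject exercise-test series
#'
#' A subject series is one exercise test: one row per exercise stage, ordered
#' by heart rate. It is stored as a tibble with the documented column set and
#' carries the subject id and free-text notes as attributes.
#'
#' @param data a data frame with (a subset of) the documented columns;
#'   missing optional columns are added as `NA`.
#' @param subject_id subject identifier; defaults to the one found in `data`.
#' @param notes free-text metadata.
#' @return a `subject_series` tibble sorted by heart rate.
#' @export
subject_series <- function(data, subject_id = NULL, notes = "") {
  data <- tibble::as_tibble(data)
  missing_opt <- setdiff(SUBJECT_COLUMNS, names(data))
  if (length(bad <- intersect(missing_opt, MANDATORY_COLUMNS))) {
    stop("missing mandatory column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in missing_opt) data[[col]] <- NA_real_
  data <- data[SUBJECT_COLUMNS]
  num_cols <- setdiff(SUBJECT_COLUMNS, "subject_id")
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v) && !all(is.na(v))) {
      stop(sprintf("column `%s` must be numeric", col), call. = FALSE)
    }
    data[[col]] <- as.numeric(v)
  }
  if (is.null(subject_id)) {
    ids <- unique(data$subject_id)
    subject_id <- if (length(ids) == 1) ids else paste(ids, collapse = "+")
  }
  data <- data[order(data$heart_rate_bpm), ]
  out <- structure(data,
                   class = c("subject_series", class(tibble::tibble())),
                   subject_id = subject_id, notes = notes)
  validate_subject_series(out)
}

#' Validate a subject series against the record invariants
#'
#' Checks that heart rates are strictly increasing (no duplicate stages), all
#' populated pressures are positive, aortic systolic exceeds aortic diastolic
#' within every record, and cardiac outputs are positive where present.
#'
#' @param series a `subject_series`.
#' @return the series, invisibly usable, unchanged; errors describe the first
#'   violated invariant.
#' @export
validate_subject_series <- function(series) {
  hr <- series$heart_rate_bpm
  if (nrow(series) == 0) stop("series has no records", call. = FALSE)
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("heart rates must be finite and > 0", call. = FALSE)
  }
  if (anyDuplicated(hr)) {
    stop("duplicate heart rate(s): ",
         paste(unique(hr[duplicated(hr)]), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(hr, strictly = TRUE)) {
    stop("heart rates must be strictly increasing", call. = FALSE)
  }
  pcols <- c("brachial_sys_mmHg", "brachial_dia_mmHg", "aortic_sys_mmHg",
             "aortic_dia_mmHg", "ventricular_sys_mmHg")
  for (col in pcols) {
    v <- series[[col]]
    if (any(v[!is.na(v)] <= 0)) {
      stop(sprintf("column `%s` contains non-positive pressures", col),
           call. = FALSE)
    }
  }
  both <- !is.na(series$aortic_sys_mmHg) & !is.na(series$aortic_dia_mmHg)
  if (any(series$aortic_sys_mmHg[both] <= series$aortic_dia_mmHg[both])) {
    stop("aortic systolic must exceed aortic diastolic in every record",
         call. = FALSE)
  }
  for (col in c("doppler_co_ml_min", "numerical_co_ml_min", "ejection_time_s")) {
    v <- series[[col]]
    if (any(v[!is.na(v)] <= 0)) {
      stop(sprintf("column `%s` contains non-positive values", col),
           call. = FALSE)
    }
  }
  series
}

#' Read a subject exercise-test series from CSV
#'
#' The canonical exchange format is one CSV row per exercise stage with the
#' fixed header `subject_id, heart_rate_bpm, brachial_sys_mmHg,
#' brachial_dia_mmHg, aortic_sys_mmHg, aortic_dia_mmHg, ventricular_sys_mmHg,
#' doppler_co_ml_min, numerical_co_ml_min, ejection_time_s`. Optional values
#' (brachial pressures, numerical cardiac output, ejection time) are encoded
#' as empty fields; optional columns may be absent entirely.
#'
#' @param path path to a CSV file.
#' @return a validated, heart-rate-sorted [subject_series()].
#' @export
#' @examples
#' path <- system.file("extdata", "table3.csv", package = "mplvr")
#' read_subject_csv(path)
read_subject_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  missing_mand <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_mand)) {
    stop("missing mandatory column(s): ", paste(missing_mand, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), SUBJECT_COLUMNS)
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(names(raw), "subject_id")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column `%s`, row %d: \"%s\"",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    raw[[col]] <- v
  }
  subject_series(raw)
}

#' Write a subject series to CSV
#'
#' Inverse of [read_subject_csv()]: numeric cells are written with 6
#' significant digits and missing optional values as empty fields, so that a
#' read/write round trip is the identity to the format's precision.
#'
#' @param series a `subject_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subject_csv <- function(series, path) {
  out <- tibble::as_tibble(series)
  for (col in setdiff(SUBJECT_COLUMNS, "subject_id")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 6, format = "g"))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s: %d record(s), heart rate %g-%g bpm\n",
              attr(x, "subject_id"), nrow(x),
              min(x$heart_rate_bpm), max(x$heart_rate_bpm)))
  NextMethod()
}

#' Brachial cuff pressures to central aortic pressures
#'
#' Oscillometric brachial pressures are converted to aortic pressures through
#' fixed offsets established by simultaneous invasive measurement: aortic
#' systolic = brachial systolic + 2.25 mmHg, aortic diastolic = brachial
#' diastolic - 5.45 mmHg.
#'
#' @param brachial_systolic,brachial_diastolic cuff pressures in mmHg;
#'   systolic must exceed diastolic.
#' @param config a [hemo_config()] list supplying the offsets.
#' @return named numeric vector with `aortic_systolic` and `aortic_diastolic`
#'   (mmHg).
#' @export
#' @examples
#' brachial_to_aortic(120, 80)
brachial_to_aortic <- function(brachial_systolic, brachial_diastolic,
                               config = hemo_config()) {
  check_positive(brachial_systolic, "brachial_systolic")
  check_positive(brachial_diastolic, "brachial_diastolic")
  if (any(brachial_systolic <= brachial_diastolic)) {
    stop("brachial systolic must exceed brachial diastolic", call. = FALSE)
  }
  sys <- brachial_systolic + config$aortic_systolic_offset_mmHg
  dia <- brachial_diastolic + config$aortic_diastolic_offset_mmHg
  if (any(dia <= 0)) {
    stop("transformed aortic diastolic pressure is non-positive", call. = FALSE)
  }
  c(aortic_systolic = unname(sys), aortic_diastolic = unname(dia))
}

#' Aortic systolic pressure to peak ventricular systolic pressure
#'
#' During ejection the ventricle leads the aorta by a small, nearly constant
#' offset measured at catheterization (about 5 mmHg); peak ventricular
#' systolic pressure is aortic systolic plus that offset.
#'
#' @param aortic_systolic aortic systolic pressure in mmHg.
#' @param config a [hemo_config()] list supplying `ventricular_offset_mmHg`.
#' @return ventricular systolic pressure in mmHg.
#' @export
#' @examples
#' aortic_to_ventricular_systolic(147)
aortic_to_ventricular_systolic <- function(aortic_systolic,
                                           config = hemo_config()) {
  check_positive(aortic_systolic, "aortic_systolic")
  aortic_systolic + config$ventricular_offset_mmHg
}

#' Load a packaged in-study fixture
#'
#' Three fixtures ship with the package: `"table3"`, the subject's nine-stage
#' exercise series (heart rate 98-169 bpm with measured ventricular-systolic
#' and aortic-diastolic pressures, Doppler cardiac output and the numerically
#' simulated cardiac output); `"table1"`, the parametric aortic-root/valve
#' geometry; and `"table2"`, blood and leaflet material constants.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return a [valve_geometry_params()], [material_properties()] or
#'   [subject_series()] respectively.
#' @export
#' @examples
#' load_fixture("table3")
#' load_fixture("table1")$base_radius_mm
load_fixture <- function(name) {
  valid <- c("table1", "table2", "table3")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown fixture; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  switch(name,
    table1 = do.call(valve_geometry_params, yaml::read_yaml(
      system.file("extdata", "table1_valve_geometry.yaml", package = "mplvr"))),
    table2 = do.call(material_properties, yaml::read_yaml(
      system.file("extdata", "table2_material_properties.yaml", package = "mplvr"))),
    table3 = read_subject_csv(
      system.file("extdata", "table3.csv", package = "mplvr"))
  )
}

#' Blood and leaflet material constants
#'
#' Container for the material constants used by the ejection model (blood
#' density, and viscosity as metadata) and carried for reference (leaflet
#' Young's modulus and Poisson ratio; no leaflet mechanics is computed here).
#'
#' @param blood_viscosity_Pa_s dynamic viscosity of blood, Pa s.
#' @param blood_density_kg_m3 blood density, kg/m^3.
#' @param leaflet_young_modulus_N_m2 leaflet Young's modulus, N/m^2.
#' @param leaflet_poisson_ratio leaflet Poisson ratio, must be < 0.5.
#' @return a `material_properties` list.
#' @export
material_properties <- function(blood_viscosity_Pa_s,
                                blood_density_kg_m3,
                                leaflet_young_modulus_N_m2,
                                leaflet_poisson_ratio) {
  check_positive(blood_viscosity_Pa_s, "blood_viscosity_Pa_s")
  check_positive(blood_density_kg_m3, "blood_density_kg_m3")
  check_positive(leaflet_young_modulus_N_m2, "leaflet_young_modulus_N_m2")
  check_positive(leaflet_poisson_ratio, "leaflet_poisson_ratio")
  if (leaflet_poisson_ratio >= 0.5) {
    stop("leaflet_poisson_ratio must be < 0.5", call. = FALSE)
  }
  structure(list(blood_viscosity_Pa_s = blood_viscosity_Pa_s,
                 blood_density_kg_m3 = blood_density_kg_m3,
                 leaflet_young_modulus_N_m2 = leaflet_young_modulus_N_m2,
                 leaflet_poisson_ratio = leaflet_poisson_ratio),
            class = "material_properties")
}
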