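# Shared constants and small helpers.

# mmHg -> Pa conversion used everywhere a pressure enters SI computation.
MMHG_TO_PA <- 133.322

#' Default transform and ejection-phase configuration
#'
#' Reads the packaged YAML configuration holding the pressure-transform
#' offsets (brachial to aortic, aortic to ventricular), the aortic waveform
#' pulse fraction, and the linear systolic-ejection-period model. Individual
#' entries can be overridden through `...`.
#'
#' @param ... named overrides for configuration entries.
#' @param path optional path to an alternative YAML configuration.
#' @return a named list of configuration values.
#' @export
#' @examples
#' hemo_config()$ventricular_offset_mmHg
#' hemo_config(aortic_pulse_fraction = 0.4)$aortic_pulse_fraction
hemo_config <- function(..., path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "mplvr")
  }
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown configuration entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg
}

# Stop unless all values are finite and strictly positive.
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

#' Systolic ejection time as a linear function of heart rate
#'
#' Standard clinical regression form for the systolic ejection period,
#' `ET = a + b * HR`, clamped to a physiological window. Used whenever a
#' subject record carries no measured ejection time.
#'
#' @param heart_rate heart rate in beats/min.
#' @param intercept,slope linear model coefficients (seconds, seconds/bpm).
#' @param clamp two-element vector of lower/upper bounds in seconds.
#' @return ejection time in seconds, same length as `heart_rate`.
#' @export
#' @examples
#' ejection_time_model(c(98, 169))
ejection_time_model <- function(heart_rate,
                                intercept = 0.413,
                                slope = -0.0017,
                                clamp = c(0.15, 0.40)) {
  check_positive(heart_rate, "heart_rate")
  pmin(pmax(intercept + slope * heart_rate, clamp[1]), clamp[2])
}
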