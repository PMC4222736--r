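# Synthetic subject generator. Emulates the statistical structure the
# pipeline assumes — a smooth concave cardiac-output-vs-heart-rate relation,
# monotone ventricular systolic pressure and U-shaped aortic diastolic
# pressure as quadratics in cardiac output — plus i.i.d. Gaussian measurement
# noise, with the noise-free CO standing in for the numerically simulated
# column. Used for parameter-recovery and robustness tests; it is not a
# closed-loop circulation model.

#' Configuration for the synthetic subject generator
#'
#' Defaults bracket the packaged subject: heart rate 95-170 beats/min,
#' cardiac output about 11-19 L/min, ventricular systolic pressure about
#' 150-190 mmHg, with the true quadratic coefficients set to the refitted
#' relations of the packaged series. Default noise levels are 150 ml/min on
#' Doppler CO and 1 mmHg on pressures, matching the scatter of the packaged
#' series about its fits.
#'
#' @param seed RNG seed; one pseudo-random stream per series.
#' @param n_records number of exercise stages, at least 4.
#' @param hr_range heart-rate interval, beats/min; stages evenly spaced.
#' @param true_cod_coeffs `c(c2, c1, c0)` of the concave (c2 < 0) Doppler
#'   CO-vs-heart-rate quadratic, ml/min.
#' @param true_vsp_coeffs,true_adp_coeffs `c(c2, c1, c0)` of the pressure
#'   quadratics in CO, mmHg.
#' @param noise_sd_co Gaussian SD of Doppler CO noise, ml/min.
#' @param noise_sd_pressure Gaussian SD of pressure noise, mmHg.
#' @param ejection_time_model `c(intercept_s, slope_s_per_bpm)` of the linear
#'   ejection-time model used to fill the ejection-time column.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1729,
                         n_records = 9,
                         hr_range = c(95, 170),
                         true_cod_coeffs = c(-0.7534, 300.73, -10713.6),
                         true_vsp_coeffs = c(-4.4967e-9, 3.86804e-3, 110.558),
                         true_adp_coeffs = c(2.56037e-7, -7.78791e-3, 122.324),
                         noise_sd_co = 150,
                         noise_sd_pressure = 1,
                         ejection_time_model = c(0.413, -0.0017)) {
  if (n_records < 4) stop("n_records must be >= 4", call. = FALSE)
  if (noise_sd_co < 0 || noise_sd_pressure < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (length(hr_range) != 2 || hr_range[1] <= 0 || hr_range[2] <= hr_range[1]) {
    stop("hr_range must be an increasing positive interval", call. = FALSE)
  }
  if (true_cod_coeffs[1] >= 0) {
    stop("true_cod_coeffs must describe a concave relation (c2 < 0)",
         call. = FALSE)
  }
  structure(list(seed = seed, n_records = n_records, hr_range = hr_range,
                 true_cod_coeffs = true_cod_coeffs,
                 true_vsp_coeffs = true_vsp_coeffs,
                 true_adp_coeffs = true_adp_coeffs,
                 noise_sd_co = noise_sd_co,
                 noise_sd_pressure = noise_sd_pressure,
                 ejection_time_model = ejection_time_model),
            class = "synth_config")
}

eval_quad <- function(cf, x) cf[1] * x^2 + cf[2] * x + cf[3]

#' Generate a synthetic subject series
#'
#' Heart rates are evenly spaced on the configured range. Doppler CO is the
#' true quadratic plus Gaussian noise; VSP and ADP are the true pressure
#' quadratics evaluated at the noise-free CO, plus Gaussian noise; the
#' numerical-CO column is the noise-free CO. Aortic systolic pressure is set
#' to VSP minus the standard ventricular offset so the series passes record
#' validation. Fully reproducible for a fixed seed, which is recorded in the
#' series notes and in the attached ground truth.
#'
#' @param config a [synth_config()].
#' @return a [subject_series()] with attribute `ground_truth`: a list holding
#'   the true coefficient vectors, the noise-free CO, and the seed.
#' @export
#' @examples
#' s <- generate_series(synth_config(seed = 1))
#' attr(s, "ground_truth")$seed
generate_series <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  hr <- seq(config$hr_range[1], config$hr_range[2],
            length.out = config$n_records)
  co_true <- eval_quad(config$true_cod_coeffs, hr)
  if (any(co_true <= 0)) {
    stop("configuration produces non-positive cardiac output over hr_range",
         call. = FALSE)
  }
  cod <- co_true + rnorm(config$n_records, 0, config$noise_sd_co)
  if (any(cod <= 0)) {
    stop("noise draw produced non-positive Doppler cardiac output",
         call. = FALSE)
  }
  vsp <- eval_quad(config$true_vsp_coeffs, co_true) +
    rnorm(config$n_records, 0, config$noise_sd_pressure)
  adp <- eval_quad(config$true_adp_coeffs, co_true) +
    rnorm(config$n_records, 0, config$noise_sd_pressure)
  offset <- hemo_config()$ventricular_offset_mmHg
  et <- ejection_time_model(hr, config$ejection_time_model[1],
                            config$ejection_time_model[2])
  series <- subject_series(tibble::tibble(
    subject_id = sprintf("synthetic_seed%d", config$seed),
    heart_rate_bpm = hr,
    aortic_sys_mmHg = vsp - offset,
    aortic_dia_mmHg = adp,
    ventricular_sys_mmHg = vsp,
    doppler_co_ml_min = cod,
    numerical_co_ml_min = co_true,
    ejection_time_s = et
  ), notes = sprintf("synthetic series, seed %d", config$seed))
  attr(series, "ground_truth") <- list(
    true_cod_coeffs = config$true_cod_coeffs,
    true_vsp_coeffs = config$true_vsp_coeffs,
    true_adp_coeffs = config$true_adp_coeffs,
    co_true_ml_min = co_true,
    seed = config$seed
  )
  series
}

#' Generate a deterministic ejection-velocity trace
#'
#' Sampled test waveform with exact peak and duration: `"halfsine"` is
#' `peak * sin(pi t / T)`, `"triangle"` ramps linearly to the peak at `T/2`
#' and back to zero.
#'
#' @param peak peak velocity, m/s.
#' @param ejection_time duration, s.
#' @param shape `"halfsine"` or `"triangle"`.
#' @param n_samples number of samples, at least 16; even counts are rounded
#'   up to the next odd value so the waveform apex lies exactly on the grid.
#' @return a [velocity_trace()].
#' @export
#' @examples
#' velocity_time_integral(generate_velocity_trace(1, 0.3, "halfsine", 1000))
generate_velocity_trace <- function(peak, ejection_time,
                                    shape = c("halfsine", "triangle"),
                                    n_samples = 256) {
  shape <- match.arg(shape)
  check_positive(peak, "peak")
  check_positive(ejection_time, "ejection_time")
  if (n_samples < 16) stop("n_samples must be >= 16", call. = FALSE)
  # an odd count puts the apex exactly on the grid; round even counts up
  if (n_samples %% 2 == 0) n_samples <- n_samples + 1
  t <- seq(0, ejection_time, length.out = n_samples)
  v <- switch(shape,
    halfsine = peak * sin(pi * t / ejection_time),
    triangle = peak * (1 - abs(2 * t / ejection_time - 1))
  )
  velocity_trace(t, v)
}
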