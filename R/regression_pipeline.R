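# The statistical chain: quadratic fits of pressure on cardiac output and of
# cardiac output on heart rate, linear inter-method cardiac-output transforms
# (Christie regressions), their composition into per-method CO(HR) curves,
# per-method pressure-vs-heart-rate prediction, and the exercise summary
# (increments, percent changes, endpoint gradients).
#
# Fits are always re-estimated from data, never transcribed from published
# coefficient tables: a least-squares refit of the packaged series is the
# authoritative representation of each relation.

#' Ordinary least-squares quadratic fit
#'
#' Fits `y = c2 x^2 + c1 x + c0` by OLS and records the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` on the fitted data together with
#' the fitted input range (evaluation outside it is flagged as extrapolation
#' by [predict.quadratic_fit()]).
#'
#' @param x,y numeric vectors, at least 4 points, `x` not all equal.
#' @param input_name,output_name axis labels carried for reporting.
#' @return a `quadratic_fit` with fields `c2`, `c1`, `c0`, `r_squared`,
#'   `input_name`, `output_name`, `input_range`.
#' @export
#' @examples
#' t3 <- load_fixture("table3")
#' fit_quadratic(t3$numerical_co_ml_min, t3$ventricular_sys_mmHg,
#'               "co_ml_min", "vsp_mmHg")$r_squared
fit_quadratic <- function(x, y, input_name = "x", output_name = "y") {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4) {
    stop("at least 4 points required for a quadratic fit", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design: x values do not support a quadratic",
         call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(c2 = unname(coef(fit)[3]), c1 = unname(coef(fit)[2]),
                 c0 = unname(coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 input_name = input_name, output_name = output_name,
                 input_range = range(x)),
            class = "quadratic_fit")
}

#' Evaluate a quadratic fit
#'
#' @param object a `quadratic_fit`.
#' @param newdata numeric vector of input values.
#' @param warn_extrapolation warn when inputs fall outside the fitted range.
#' @param ... unused.
#' @return fitted values, numeric.
#' @export
predict.quadratic_fit <- function(object, newdata,
                                  warn_extrapolation = TRUE, ...) {
  if (warn_extrapolation &&
      any(newdata < object$input_range[1] | newdata > object$input_range[2])) {
    warning(sprintf("extrapolating %s outside fitted range [%g, %g]",
                    object$input_name, object$input_range[1],
                    object$input_range[2]), call. = FALSE)
  }
  object$c2 * newdata^2 + object$c1 * newdata + object$c0
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> %s = %.6g %s^2 + %.6g %s + %.6g  (R^2 = %.4f)\n",
              x$output_name, x$c2, x$input_name, x$c1, x$input_name, x$c0,
              x$r_squared))
  invisible(x)
}

#' Linear inter-method cardiac-output transforms
#'
#' The Christie regressions relate invasively measured cardiac output to the
#' Doppler estimate across subjects: thermodilution
#' `COT = 1.41 COD - 2394` and Fick-oximetric `COF = 1.03 COD + 2165`
#' (ml/min). `christie_map()` returns the published map for a method;
#' `linear_map()` builds an arbitrary one.
#'
#' @param method `"thermodilution"` or `"fick"`.
#' @return a `linear_map` with `slope`, `intercept`, `method_name`.
#' @export
#' @examples
#' christie_transform(11356, christie_map("thermodilution"))
christie_map <- function(method = c("thermodilution", "fick")) {
  method <- match.arg(method)
  switch(method,
    thermodilution = linear_map(1.41, -2394, "thermodilution"),
    fick = linear_map(1.03, 2165, "fick"))
}

#' @rdname christie_map
#' @param slope dimensionless slope, must be positive.
#' @param intercept intercept in ml/min.
#' @param method_name label.
#' @export
linear_map <- function(slope, intercept, method_name = "custom") {
  check_positive(slope, "slope")
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 method_name = method_name), class = "linear_map")
}

#' @rdname christie_map
#' @param cod Doppler cardiac output, ml/min, positive.
#' @param map a `linear_map`.
#' @export
christie_transform <- function(cod, map) {
  stopifnot(inherits(map, "linear_map"))
  check_positive(cod, "cod")
  out <- map$slope * cod + map$intercept
  if (any(out <= 0)) {
    stop("transformed cardiac output is non-positive: outside the map's ",
         "validity range", call. = FALSE)
  }
  out
}

#' Compose a CO-vs-heart-rate fit with an inter-method map
#'
#' Applying a linear map `a x + b` to a quadratic fit is itself quadratic:
#' coefficients `(a c2, a c1, a c0 + b)`. The coefficient of determination is
#' invariant under a positive-slope linear map of the response, so the
#' composed fit carries the original `r_squared` unchanged.
#'
#' @param cod_fit a `quadratic_fit` mapping heart rate to Doppler CO.
#' @param map a `linear_map` (e.g. [christie_map()]).
#' @return a `quadratic_fit` mapping heart rate to the mapped method's CO.
#' @export
compose_co_vs_hr <- function(cod_fit, map) {
  stopifnot(inherits(cod_fit, "quadratic_fit"), inherits(map, "linear_map"))
  structure(list(c2 = map$slope * cod_fit$c2,
                 c1 = map$slope * cod_fit$c1,
                 c0 = map$slope * cod_fit$c0 + map$intercept,
                 r_squared = cod_fit$r_squared,
                 input_name = cod_fit$input_name,
                 output_name = paste0(map$method_name, "_co"),
                 input_range = cod_fit$input_range),
            class = "quadratic_fit")
}

#' Predict a pressure curve over a heart-rate grid
#'
#' Evaluates the pointwise composition `pressure_fit(method_co_vs_hr(hr))`:
#' heart rate to method cardiac output to pressure.
#'
#' @param pressure_fit a `quadratic_fit` of pressure on cardiac output.
#' @param method_co_vs_hr a `quadratic_fit` of cardiac output on heart rate
#'   (Doppler, or composed through [compose_co_vs_hr()]).
#' @param hr_grid heart rates in beats/min; non-empty. Values outside the
#'   fitted heart-rate range are flagged with a warning, not refused.
#' @return a tibble with `heart_rate_bpm`, `co_ml_min`, `pressure_mmHg`.
#' @export
predict_pressure_curve <- function(pressure_fit, method_co_vs_hr, hr_grid) {
  if (length(hr_grid) == 0) stop("empty heart-rate grid", call. = FALSE)
  co <- predict(method_co_vs_hr, hr_grid)
  p <- predict(pressure_fit, co, warn_extrapolation = FALSE)
  tibble::tibble(heart_rate_bpm = hr_grid, co_ml_min = co, pressure_mmHg = p)
}

#' Fit the full regression chain of a subject series
#'
#' Convenience constructor for the three quadratic relations the pipeline
#' uses: ventricular systolic pressure and aortic diastolic pressure on
#' cardiac output (the numerically simulated column by default, falling back
#' to an ejection-model fill-in when absent and `allow_surrogate` is set),
#' and Doppler cardiac output on heart rate.
#'
#' @param series a [subject_series()].
#' @param allow_surrogate if `TRUE` and `numerical_co_ml_min` is missing,
#'   fill it with [simulate_ejection()] output at the calibrated defaults.
#' @param params [surrogate_params()] used for the fill-in.
#' @return a list with `vsp_fit`, `adp_fit`, `cod_fit`.
#' @export
#' @examples
#' fits <- fit_pressure_chain(load_fixture("table3"))
#' fits$vsp_fit
fit_pressure_chain <- function(series, allow_surrogate = FALSE,
                               params = surrogate_params()) {
  co <- series$numerical_co_ml_min
  if (any(is.na(co))) {
    if (!allow_surrogate) {
      stop("numerical_co_ml_min is missing; set allow_surrogate = TRUE to ",
           "fill it with the ejection model", call. = FALSE)
    }
    miss <- is.na(co)
    co[miss] <- series_model_co(
      subject_series(tibble::as_tibble(series)[miss, ],
                     subject_id = attr(series, "subject_id")), params)
  }
  list(
    vsp_fit = fit_quadratic(co, series$ventricular_sys_mmHg,
                            "co_ml_min", "vsp_mmHg"),
    adp_fit = fit_quadratic(co, series$aortic_dia_mmHg,
                            "co_ml_min", "adp_mmHg"),
    cod_fit = fit_quadratic(series$heart_rate_bpm, series$doppler_co_ml_min,
                            "heart_rate_bpm", "doppler_co_ml_min")
  )
}

#' Exercise summary: increments, percent changes and endpoint gradients
#'
#' Summarizes how ventricular systolic pressure (VSP) and aortic diastolic
#' pressure (ADP) change between the lowest and highest recorded heart rates,
#' per cardiac-output convention:
#'
#' * Doppler entries use the measured pressures at the two endpoint records;
#' * Fick and thermodilution entries evaluate the fitted VSP(CO)/ADP(CO)
#'   quadratics at the Christie-transformed measured Doppler CO of those same
#'   two records.
#'
#' Percent change is relative to the low-heart-rate value; the endpoint
#' gradient is the difference quotient `absolute_change / (hr_max - hr_min)`
#' (not a regression slope). Raw values are returned;
#' [format_exercise_summary()] applies the reporting convention (integer
#' percents, two-decimal gradients).
#'
#' @param series a [subject_series()] spanning at least 2 heart rates with
#'   measured pressures and Doppler CO.
#' @param fits list with `vsp_fit` and `adp_fit` (see
#'   [fit_pressure_chain()]); defaults to refitting `series`.
#' @param maps list of `linear_map`s for the invasive methods.
#' @return an `exercise_summary` tibble: `method`, `pressure`, `hr_min`,
#'   `hr_max`, `value_low_mmHg`, `value_high_mmHg`, `absolute_change_mmHg`,
#'   `percent_change`, `endpoint_gradient_mmHg_per_bpm`.
#' @export
#' @examples
#' exercise_summary(load_fixture("table3"))
exercise_summary <- function(series,
                             fits = fit_pressure_chain(series),
                             maps = list(christie_map("fick"),
                                         christie_map("thermodilution"))) {
  if (nrow(series) < 2) {
    stop("summary needs at least 2 distinct heart rates", call. = FALSE)
  }
  need <- c("ventricular_sys_mmHg", "aortic_dia_mmHg", "doppler_co_ml_min")
  bad <- need[vapply(need, function(c2) any(is.na(series[[c2]])), logical(1))]
  if (length(bad)) {
    stop("missing required column value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lo <- 1L; hi <- nrow(series)
  hr <- series$heart_rate_bpm[c(lo, hi)]
  row_of <- function(method, pressure, v) {
    tibble::tibble(method = method, pressure = pressure,
                   hr_min = hr[1], hr_max = hr[2],
                   value_low_mmHg = v[1], value_high_mmHg = v[2],
                   absolute_change_mmHg = v[2] - v[1],
                   percent_change = 100 * (v[2] - v[1]) / v[1],
                   endpoint_gradient_mmHg_per_bpm = (v[2] - v[1]) / diff(hr))
  }
  out <- rbind(
    row_of("doppler", "vsp", series$ventricular_sys_mmHg[c(lo, hi)]),
    row_of("doppler", "adp", series$aortic_dia_mmHg[c(lo, hi)])
  )
  cod <- series$doppler_co_ml_min[c(lo, hi)]
  for (map in maps) {
    co <- christie_transform(cod, map)
    out <- rbind(
      out,
      row_of(map$method_name, "vsp",
             predict(fits$vsp_fit, co, warn_extrapolation = FALSE)),
      row_of(map$method_name, "adp",
             predict(fits$adp_fit, co, warn_extrapolation = FALSE))
    )
  }
  structure(out, class = c("exercise_summary", class(tibble::tibble())))
}

#' Format an exercise summary with the reporting conventions
#'
#' Rounds for human-readable reporting: pressures and absolute changes to one
#' decimal, percent changes to the nearest integer (with a one-decimal
#' column alongside), endpoint gradients to two decimals.
#'
#' @param summary an [exercise_summary()].
#' @return a tibble with rounded reporting columns.
#' @export
format_exercise_summary <- function(summary) {
  tibble::tibble(
    method = summary$method,
    pressure = summary$pressure,
    absolute_change_mmHg = round(summary$absolute_change_mmHg, 1),
    percent_change = round(summary$percent_change),
    percent_change_1dp = round(summary$percent_change, 1),
    endpoint_gradient_mmHg_per_bpm =
      round(summary$endpoint_gradient_mmHg_per_bpm, 2)
  )
}
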