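# Doppler-derived hemodynamics: velocity-time integral, aortic area, stroke
# volume, cardiac output and mean ejection velocity. Internal units are SI
# (m, s); volumes convert to ml / ml/min at the reporting boundary.

#' Sampled ejection-velocity trace
#'
#' A velocity trace is the sampled outflow-velocity waveform over one
#' ejection period: strictly increasing times starting at 0, velocities in
#' m/s; the ejection time is the last time point.
#'
#' @param times sample times in seconds, strictly increasing, `times[1] == 0`.
#' @param velocities velocities in m/s, same length as `times`.
#' @return a `velocity_trace` list with `times`, `velocities`,
#'   `ejection_time`.
#' @export
velocity_trace <- function(times, velocities) {
  if (length(times) < 2) stop("at least 2 samples required", call. = FALSE)
  if (length(times) != length(velocities)) {
    stop("times and velocities must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(velocities))) {
    stop("trace contains non-finite values", call. = FALSE)
  }
  if (abs(times[1]) > .Machine$double.eps) {
    stop("trace must start at time 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, velocities = velocities,
                 ejection_time = times[length(times)]),
            class = "velocity_trace")
}

#' Read/write a velocity trace as two-column CSV
#'
#' Traces are exchanged as CSV with columns `time_s, velocity_m_s`.
#'
#' @param path file path.
#' @return `read_velocity_csv` returns a [velocity_trace()];
#'   `write_velocity_csv` returns `path` invisibly.
#' @export
read_velocity_csv <- function(path) {
  d <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!identical(names(d), c("time_s", "velocity_m_s"))) {
    stop("expected columns `time_s, velocity_m_s`", call. = FALSE)
  }
  velocity_trace(d$time_s, d$velocity_m_s)
}

#' @rdname read_velocity_csv
#' @param trace a [velocity_trace()].
#' @export
write_velocity_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(time_s = trace$times,
                                  velocity_m_s = trace$velocities),
                   path, progress = FALSE)
  invisible(path)
}

#' Aortic cross-sectional area from diameter
#'
#' Circular cross-section at the sinotubular junction: `pi * (D/2)^2`.
#'
#' @param diameter ascending aortic diameter in metres.
#' @return area in m^2.
#' @export
#' @examples
#' aortic_area(0.023)
aortic_area <- function(diameter) {
  check_positive(diameter, "diameter")
  pi * (diameter / 2)^2
}

#' Velocity-time integral of an ejection trace
#'
#' Trapezoidal integral of velocity over the ejection period on the supplied
#' grid (no resampling); linear in the velocity values with discretization
#' error quadratic in the step size.
#'
#' @param trace a [velocity_trace()].
#' @return VTI in metres.
#' @export
#' @examples
#' tr <- generate_velocity_trace(1, 0.3, "halfsine", 1000)
#' velocity_time_integral(tr)  # ~ 2 * peak * T / pi
velocity_time_integral <- function(trace) {
  stopifnot(inherits(trace, "velocity_trace"))
  pracma::trapz(trace$times, trace$velocities)
}

#' Stroke volume from VTI and aortic area
#'
#' The Doppler stroke-volume estimate: the velocity-time integral times the
#' aortic cross-sectional area, reported in millilitres.
#'
#' @param vti velocity-time integral in metres.
#' @param area aortic cross-sectional area in m^2.
#' @return stroke volume in ml.
#' @export
#' @examples
#' stroke_volume(0.30, 3.1416e-4)
stroke_volume <- function(vti, area) {
  check_positive(vti, "vti")
  check_positive(area, "area")
  vti * area * 1e6
}

#' Cardiac output from stroke volume and heart rate
#'
#' @param stroke_volume stroke volume in ml.
#' @param heart_rate heart rate in beats/min.
#' @return cardiac output in ml/min.
#' @export
#' @examples
#' cardiac_output(115.88, 98)
cardiac_output <- function(stroke_volume, heart_rate) {
  check_positive(stroke_volume, "stroke_volume")
  check_positive(heart_rate, "heart_rate")
  stroke_volume * heart_rate
}

#' Mean ejection velocity
#'
#' VTI divided by the ejection time.
#'
#' @param vti velocity-time integral in metres.
#' @param ejection_time ejection time in seconds.
#' @return mean velocity in m/s.
#' @export
mean_velocity <- function(vti, ejection_time) {
  check_positive(vti, "vti")
  check_positive(ejection_time, "ejection_time")
  vti / ejection_time
}

#' Summarize a velocity trace into the Doppler flow quantities
#'
#' Convenience wrapper running the full Doppler chain on one trace: VTI,
#' stroke volume, cardiac output and mean velocity for a given aortic
#' diameter and heart rate.
#'
#' @param trace a [velocity_trace()].
#' @param diameter ascending aortic diameter in metres.
#' @param heart_rate heart rate in beats/min.
#' @return a `flow_summary` tibble row with columns `vti_m`,
#'   `aortic_diameter_m`, `aortic_area_m2`, `stroke_volume_ml`,
#'   `cardiac_output_ml_min`, `mean_velocity_m_s`.
#' @export
flow_summary <- function(trace, diameter, heart_rate) {
  vti <- velocity_time_integral(trace)
  area <- aortic_area(diameter)
  sv <- stroke_volume(vti, area)
  tibble::tibble(
    vti_m = vti,
    aortic_diameter_m = diameter,
    aortic_area_m2 = area,
    stroke_volume_ml = sv,
    cardiac_output_ml_min = cardiac_output(sv, heart_rate),
    mean_velocity_m_s = mean_velocity(vti, trace$ejection_time)
  )
}
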