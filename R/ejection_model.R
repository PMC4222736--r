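# Reduced-order surrogate of aortic-valve ejection. The leaflet mechanics of
# a full fluid-structure simulation are abstracted into a scalar opening
# state zeta in [0, 1] driven by the transvalvular pressure difference; flow
# through the effective orifice obeys an orifice/inertance momentum balance:
#
#   dzeta/dt = k_open * dP * (1 - zeta)   if dP >= 0
#            = k_close * dP * zeta        otherwise
#   A(zeta)  = A_min + (A_max - A_min) * zeta
#   rho * l_eff / A * dQ/dt + rho / (2 A^2) * Q |Q| = dP      (dP in Pa)
#
# with zeta(0) = 0, Q(0) = 0. Integrated with classical RK4 on a fixed grid.

#' Surrogate parameters for the ejection model
#'
#' @param k_open,k_close opening/closing rate constants, 1/(Pa s). The
#'   pressure difference is non-negative over the whole ejection window under
#'   the default waveforms, so `k_close` only acts on inputs with reverse
#'   loading.
#' @param effective_length effective inertial length of the blood column
#'   through the valve, m.
#' @param area_max maximum effective orifice area, m^2; defaults to the
#'   annulus area of the packaged valve geometry.
#' @param area_min_fraction leakage area as a fraction of `area_max`, in
#'   (0, 0.05].
#' @param blood_density blood density, kg/m^3; default from the packaged
#'   material constants.
#'
#' @details Default rate/length values are the calibrated point obtained by
#' [calibrate_ejection()] on the packaged subject series (seed 1729); see the
#' methods vignette for the fit quality actually achieved.
#'
#' @return a `surrogate_params` list.
#' @export
surrogate_params <- function(k_open = 1.39e-3,
                             k_close = 1.39e-3,
                             effective_length = 1.06e-3,
                             area_max = pi * 0.0115^2,
                             area_min_fraction = 0.05,
                             blood_density = 1056) {
  p <- list(k_open = k_open, k_close = k_close,
            effective_length = effective_length, area_max = area_max,
            area_min_fraction = area_min_fraction,
            blood_density = blood_density)
  for (nm in names(p)) check_positive(p[[nm]], nm)
  if (area_min_fraction > 0.05) {
    stop("area_min_fraction must lie in (0, 0.05]", call. = FALSE)
  }
  structure(p, class = "surrogate_params")
}

#' Pressure-load boundary conditions for one ejection phase
#'
#' Builds the ventricular and aortic pressure waveforms over one ejection
#' window from a record's peak ventricular systolic pressure (VSP) and aortic
#' diastolic pressure (ADP). Both are half-sine bumps on the ADP baseline:
#' the ventricular side rises to VSP at mid-ejection, the aortic side rises
#' by a fixed fraction of the pulse (default 0.35), so the transvalvular
#' difference is non-negative and vanishes at the window's ends.
#'
#' @param vsp peak ventricular systolic pressure, mmHg.
#' @param adp aortic diastolic pressure (waveform baseline), mmHg.
#' @param ejection_time ejection window length, s.
#' @param heart_rate heart rate, beats/min.
#' @param pulse_fraction aortic amplitude as a fraction of `vsp - adp`.
#' @return an `ejection_bc` list with `ventricular_pressure(t)` and
#'   `aortic_pressure(t)` (mmHg), `ejection_time`, `heart_rate`, `vsp`,
#'   `adp`.
#' @export
#' @examples
#' bc <- build_waveforms(152, 68, 0.30, 98)
#' bc$ventricular_pressure(0.15)
build_waveforms <- function(vsp, adp, ejection_time, heart_rate,
                            pulse_fraction = hemo_config()$aortic_pulse_fraction) {
  check_positive(adp, "adp")
  check_positive(ejection_time, "ejection_time")
  check_positive(heart_rate, "heart_rate")
  if (vsp <= adp) {
    stop("vsp must exceed adp to define an ejection load", call. = FALSE)
  }
  pulse <- vsp - adp
  tt <- ejection_time
  structure(list(
    ventricular_pressure = function(t) adp + pulse * sin(pi * t / tt),
    aortic_pressure = function(t) adp + pulse_fraction * pulse * sin(pi * t / tt),
    ejection_time = ejection_time, heart_rate = heart_rate,
    vsp = vsp, adp = adp, pulse_fraction = pulse_fraction
  ), class = "ejection_bc")
}

#' Simulate one ejection phase
#'
#' Integrates the opening-state/flow ODE system over the ejection window with
#' classical fourth-order Runge-Kutta on a fixed grid, and summarizes the
#' trajectory into stroke volume (forward flow only) and cardiac output.
#'
#' @param bc an [build_waveforms()] boundary-condition object.
#' @param params a [surrogate_params()] set.
#' @param dt time step, s; must satisfy `dt <= ejection_time / 200`.
#' @return an `ejection_result` list: `times` (s), `flow` (m^3/s),
#'   `opening_state` (in `[0, 1]`), `stroke_volume` (ml), `cardiac_output`
#'   (ml/min).
#' @export
#' @examples
#' bc <- build_waveforms(152, 68, 0.2464, 98)
#' simulate_ejection(bc, surrogate_params())$cardiac_output
simulate_ejection <- function(bc, params, dt = bc$ejection_time / 400) {
  stopifnot(inherits(bc, "ejection_bc"), inherits(params, "surrogate_params"))
  tt <- bc$ejection_time
  if (dt > tt / 200) {
    stop(sprintf("dt too coarse: need dt <= ejection_time/200 = %g s", tt / 200),
         call. = FALSE)
  }
  n <- ceiling(tt / dt)
  times <- seq(0, tt, length.out = n + 1)
  amax <- params$area_max
  amin <- params$area_min_fraction * amax
  rho <- params$blood_density
  leff <- params$effective_length
  ko <- params$k_open; kc <- params$k_close
  pv <- bc$ventricular_pressure; pa <- bc$aortic_pressure
  rhs <- function(t, y, parms) {
    dp <- (pv(t) - pa(t)) * MMHG_TO_PA
    z <- min(max(y[1], 0), 1)
    a <- amin + (amax - amin) * z
    dz <- if (dp >= 0) ko * dp * (1 - z) else kc * dp * z
    dq <- (dp - rho / (2 * a^2) * y[2] * abs(y[2])) * a / (rho * leff)
    list(c(dz, dq))
  }
  sol <- deSolve::ode(y = c(zeta = 0, q = 0), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  zeta <- sol[, "zeta"]; q <- sol[, "q"]
  if (any(!is.finite(zeta)) || any(!is.finite(q))) {
    t_bad <- times[which(!is.finite(zeta) | !is.finite(q))[1]]
    stop(sprintf("integration produced non-finite state at t = %g s", t_bad),
         call. = FALSE)
  }
  zeta <- pmin(pmax(zeta, 0), 1)
  sv_ml <- pracma::trapz(times, pmax(q, 0)) * 1e6
  structure(list(times = times, flow = q, opening_state = zeta,
                 stroke_volume = sv_ml,
                 cardiac_output = sv_ml * bc$heart_rate),
            class = "ejection_result")
}

# Model cardiac output for each record of a series: build boundary conditions
# from measured VSP/ADP, take ejection time from the record or the linear
# heart-rate model, simulate, return ml/min per record.
series_model_co <- function(series, params, n_steps = 400,
                            config = hemo_config()) {
  et <- series$ejection_time_s
  miss <- is.na(et)
  et[miss] <- ejection_time_model(
    series$heart_rate_bpm[miss],
    intercept = config$ejection_time_intercept_s,
    slope = config$ejection_time_slope_s_per_bpm,
    clamp = config$ejection_time_clamp_s)
  vapply(seq_len(nrow(series)), function(i) {
    bc <- build_waveforms(series$ventricular_sys_mmHg[i],
                          series$aortic_dia_mmHg[i],
                          et[i], series$heart_rate_bpm[i],
                          pulse_fraction = config$aortic_pulse_fraction)
    simulate_ejection(bc, params, dt = et[i] / n_steps)$cardiac_output
  }, numeric(1))
}

#' Calibrate the ejection surrogate against a subject series
#'
#' Bounded least-squares fit of the surrogate's free parameters (`k_open`,
#' `k_close`, `effective_length`, `area_min_fraction`) so that the model's
#' cardiac output matches the series' numerically simulated cardiac-output
#' column. The objective (sum of squared CO errors, ml/min) is minimized with
#' a box-constrained quasi-Newton search from a fixed-seed Latin-hypercube
#' multistart in log-parameter space; deterministic for a fixed seed.
#'
#' @param series a [subject_series()] with `numerical_co_ml_min` populated for
#'   at least 4 records.
#' @param params0 starting parameter set; also supplies the fixed `area_max`
#'   and `blood_density`.
#' @param bounds named list of finite `c(lower, upper)` intervals for the four
#'   free parameters. The default lower bound on `effective_length` (1 mm)
#'   keeps the blood-column inertance physically plausible and keeps the
#'   orifice relaxation time resolvable by the explicit integration grid.
#' @param n_starts number of multistart points (in addition to `params0`).
#' @param seed RNG seed for the multistart design.
#' @param n_steps RK4 steps per ejection window during calibration.
#' @param config a [hemo_config()] list (waveform fraction, ejection-time
#'   model).
#' @return a `calibration_result` list: `params` (calibrated
#'   [surrogate_params()]), `residuals` (tibble with per-record model CO,
#'   target CO and relative residual), `objective` (SSE, (ml/min)^2),
#'   `max_abs_rel_residual`, `convergence` (optimizer codes per start) and
#'   `seed`.
#' @export
calibrate_ejection <- function(series,
                               params0 = surrogate_params(),
                               bounds = list(
                                 k_open = c(1e-5, 10),
                                 k_close = c(1e-5, 10),
                                 effective_length = c(1e-3, 1),
                                 area_min_fraction = c(1e-4, 0.05)),
                               n_starts = 8,
                               seed = 1729,
                               n_steps = 400,
                               config = hemo_config()) {
  usable <- !is.na(series$numerical_co_ml_min)
  if (sum(usable) < 4) {
    stop("calibration needs numerical_co_ml_min for at least 4 records",
         call. = FALSE)
  }
  fit_series <- subject_series(tibble::as_tibble(series)[usable, ],
                               subject_id = attr(series, "subject_id"))
  target <- fit_series$numerical_co_ml_min
  free <- c("k_open", "k_close", "effective_length", "area_min_fraction")
  if (!setequal(names(bounds), free)) {
    stop("bounds must name exactly: ", paste(free, collapse = ", "),
         call. = FALSE)
  }
  lo <- log10(vapply(bounds[free], `[`, numeric(1), 1))
  hi <- log10(vapply(bounds[free], `[`, numeric(1), 2))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("bounds must be finite positive intervals", call. = FALSE)
  }
  make_params <- function(logp) {
    p <- as.list(10^logp); names(p) <- free
    surrogate_params(k_open = p$k_open, k_close = p$k_close,
                     effective_length = p$effective_length,
                     area_max = params0$area_max,
                     area_min_fraction = p$area_min_fraction,
                     blood_density = params0$blood_density)
  }
  objective <- function(logp) {
    co <- try(series_model_co(fit_series, make_params(logp),
                              n_steps = n_steps, config = config),
              silent = TRUE)
    if (inherits(co, "try-error") || any(!is.finite(co))) return(1e12)
    sum((co - target)^2)
  }
  p0 <- pmin(pmax(log10(unlist(params0[free])), lo), hi)
  starts <- matrix(p0, nrow = 1)
  if (n_starts > 0) {
    set.seed(seed)
    u <- lhs::randomLHS(n_starts, length(free))
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`))
  }
  best <- NULL
  convergence <- integer(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::nlminb(starts[s, ], objective, lower = lo, upper = hi,
                         control = list(eval.max = 400, iter.max = 200))
    convergence[s] <- fit$convergence
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || !is.finite(best$objective) || best$objective >= 1e12) {
    stop("calibration failed to produce a finite objective", call. = FALSE)
  }
  params <- make_params(best$par)
  co <- series_model_co(fit_series, params, n_steps = n_steps, config = config)
  resid <- tibble::tibble(
    heart_rate_bpm = fit_series$heart_rate_bpm,
    co_model_ml_min = co,
    co_target_ml_min = target,
    rel_residual = (co - target) / target
  )
  structure(list(params = params, residuals = resid,
                 objective = best$objective,
                 max_abs_rel_residual = max(abs(resid$rel_residual)),
                 convergence = convergence, seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  SSE: %.4g (ml/min)^2; max |relative residual|: %.1f%%\n",
              x$objective, 100 * x$max_abs_rel_residual))
  cat(sprintf("  k_open %.3g  k_close %.3g  l_eff %.3g m  A_min/A_max %.3g\n",
              x$params$k_open, x$params$k_close,
              x$params$effective_length, x$params$area_min_fraction))
  invisible(x)
}
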