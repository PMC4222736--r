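test_that("quadratic fit recovers exact polynomials and rejects bad input", {
  x <- seq(-2, 3, length.out = 10)
  f <- fit_quadratic(x, 2 * x^2 - 3 * x + 1)
  expect_equal(c(f$c2, f$c1, f$c0), c(2, -3, 1), tolerance = 1e-9)
  expect_equal(f$r_squared, 1)
  expect_equal(f$input_range, c(-2, 3))

  expect_error(fit_quadratic(1:3, 1:3), "at least 4")
  expect_error(fit_quadratic(rep(2, 5), 1:5), "rank-deficient")
})

test_that("prediction evaluates the polynomial and flags extrapolation", {
  x <- 1:6
  f <- fit_quadratic(x, x^2)
  expect_equal(predict(f, c(2, 4)), c(4, 16), tolerance = 1e-9)
  expect_warning(predict(f, 10), "extrapolating")
  expect_silent(predict(f, 10, warn_extrapolation = FALSE))
})

test_that("Christie transforms map Doppler CO to the invasive conventions", {
  expect_equal(christie_transform(11356, christie_map("thermodilution")),
               13617.96)
  expect_equal(christie_transform(18849, christie_map("fick")), 21579.47)
  expect_equal(christie_transform(5000, linear_map(1, 0)), 5000)
  expect_error(christie_transform(1000, christie_map("thermodilution")),
               "validity range")
  expect_error(linear_map(-1, 0), "> 0")
})

test_that("composition equals the pointwise transform and preserves R^2", {
  set.seed(7)
  for (i in 1:20) {
    x <- sort(runif(8, 60, 180))
    y <- runif(1, -2, -0.1) * x^2 + runif(1, 100, 400) * x + rnorm(8, 0, 50)
    f <- fit_quadratic(x, y)
    m <- linear_map(runif(1, 0.5, 2), runif(1, -3000, 3000))
    g <- compose_co_vs_hr(f, m)
    hr <- runif(5, 60, 180)
    expect_equal(predict(g, hr, warn_extrapolation = FALSE),
                 m$slope * predict(f, hr, warn_extrapolation = FALSE) +
                   m$intercept,
                 tolerance = 1e-12)
    expect_identical(g$r_squared, f$r_squared)
    # refitting the mapped response reproduces the same R^2
    refit <- fit_quadratic(x, m$slope * y + m$intercept)
    expect_equal(refit$r_squared, f$r_squared, tolerance = 1e-12)
  }
  f <- fit_quadratic(1:5, (1:5)^2)
  expect_equal(unclass(compose_co_vs_hr(f, linear_map(1, 0)))[c("c2", "c1", "c0")],
               unclass(f)[c("c2", "c1", "c0")])
})

test_that("composed invasive CO fits match the published coefficients", {
  fits <- fit_pressure_chain(load_fixture("table3"))
  fick <- compose_co_vs_hr(fits$cod_fit, christie_map("fick"))
  expect_equal(fick$c2, -0.776, tolerance = 1e-3)
  expect_equal(fick$c1, 309, tolerance = 3e-3)
  thermo <- compose_co_vs_hr(fits$cod_fit, christie_map("thermodilution"))
  expect_equal(thermo$c2, -1.062, tolerance = 1e-3)
  expect_equal(thermo$c1, 424, tolerance = 3e-3)
  expect_equal(thermo$c0, -17500, tolerance = 1e-4 * 17500)
  expect_equal(fick$r_squared, fits$cod_fit$r_squared)
})

test_that("pressure curves follow the fitted chain on the packaged series", {
  t3 <- load_fixture("table3")
  fits <- fit_pressure_chain(t3)

  # via the measured Doppler CO at rest, thermodilution VSP is ~162.4 mmHg
  co_t <- christie_transform(11356, christie_map("thermodilution"))
  expect_equal(predict(fits$vsp_fit, co_t, warn_extrapolation = FALSE),
               162.40, tolerance = 1e-3)
  # via the composed CO(HR) fit the same point evaluates to ~163.3 mmHg
  thermo_fit <- compose_co_vs_hr(fits$cod_fit, christie_map("thermodilution"))
  curve <- predict_pressure_curve(fits$vsp_fit, thermo_fit, 98)
  expect_equal(curve$pressure_mmHg, 163.27, tolerance = 1e-3)

  const <- fits$vsp_fit
  const$c2 <- 0; const$c1 <- 0; const$c0 <- 120
  flat <- predict_pressure_curve(const, fits$cod_fit, seq(98, 169, by = 1))
  expect_equal(unique(flat$pressure_mmHg), 120)
  expect_error(predict_pressure_curve(fits$vsp_fit, fits$cod_fit, numeric(0)),
               "empty")
})

test_that("refitted relations track the measured columns", {
  t3 <- load_fixture("table3")
  fits <- fit_pressure_chain(t3)
  vsp_resid <- predict(fits$vsp_fit, t3$numerical_co_ml_min) -
    t3$ventricular_sys_mmHg
  expect_lt(max(abs(vsp_resid)), 5)
  cod_resid <- predict(fits$cod_fit, t3$heart_rate_bpm) - t3$doppler_co_ml_min
  expect_lt(max(abs(cod_resid)), 500)
  chain_resid <- predict_pressure_curve(fits$vsp_fit, fits$cod_fit,
                                        t3$heart_rate_bpm)$pressure_mmHg -
    t3$ventricular_sys_mmHg
  expect_lt(max(abs(chain_resid)), 5.1)
})

test_that("exercise summary reports all method/pressure combinations", {
  t3 <- load_fixture("table3")
  summ <- exercise_summary(t3)
  expect_equal(nrow(summ), 6)
  expect_setequal(unique(summ$method), c("doppler", "fick", "thermodilution"))
  expect_equal(summ$hr_min, rep(98, 6))
  expect_equal(summ$hr_max, rep(169, 6))
  expect_equal(summ$endpoint_gradient_mmHg_per_bpm,
               summ$absolute_change_mmHg / 71)

  missing_co <- tibble::as_tibble(t3)
  missing_co$doppler_co_ml_min[4] <- NA
  expect_error(exercise_summary(subject_series(missing_co), fits = NULL),
               "doppler_co_ml_min")
})

test_that("surrogate fill-in enables the chain when numerical CO is absent", {
  t3 <- tibble::as_tibble(load_fixture("table3"))
  t3$numerical_co_ml_min <- NA_real_
  s <- subject_series(t3)
  expect_error(fit_pressure_chain(s), "allow_surrogate")
  fits <- fit_pressure_chain(s, allow_surrogate = TRUE)
  expect_s3_class(fits$vsp_fit, "quadratic_fit")
  expect_true(is.finite(fits$vsp_fit$r_squared))
})
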