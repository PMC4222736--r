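test_that("packaged fixtures match every printed cell", {
  t3 <- load_fixture("table3")
  expect_s3_class(t3, "subject_series")
  expect_equal(nrow(t3), 9)
  for (col in names(table3_printed)) {
    expect_equal(t3[[col]], table3_printed[[col]], info = col)
  }
  # aortic systolic carried as ventricular systolic minus the 5 mmHg offset
  expect_equal(t3$aortic_sys_mmHg, t3$ventricular_sys_mmHg - 5)

  t1 <- load_fixture("table1")
  expect_s3_class(t1, "valve_geometry_params")
  for (nm in names(table1_printed)) {
    expect_equal(t1[[nm]], unname(table1_printed[nm]), info = nm)
  }

  t2 <- load_fixture("table2")
  expect_s3_class(t2, "material_properties")
  for (nm in names(table2_printed)) {
    expect_equal(t2[[nm]], unname(table2_printed[nm]), info = nm)
  }

  expect_error(load_fixture("table9"), "table1")
})

test_that("CSV read/write round-trips a valid series to format precision", {
  t3 <- load_fixture("table3")
  path <- tempfile(fileext = ".csv")
  write_subject_csv(t3, path)
  back <- read_subject_csv(path)
  for (col in setdiff(names(t3), "subject_id")) {
    expect_equal(back[[col]], t3[[col]], tolerance = 1e-5, info = col)
  }
  expect_identical(attr(back, "subject_id"), attr(t3, "subject_id"))
})

test_that("schema and invariant violations are rejected with useful messages", {
  t3 <- tibble::as_tibble(load_fixture("table3"))

  expect_error(read_subject_csv(tempfile()), "not found")

  no_hr <- t3[setdiff(names(t3), "heart_rate_bpm")]
  expect_error(read_subject_csv(write_temp_series_csv(no_hr)),
               "heart_rate_bpm")

  bad_cell <- t3
  bad_cell$doppler_co_ml_min <- as.character(bad_cell$doppler_co_ml_min)
  bad_cell$doppler_co_ml_min[3] <- "twelve"
  expect_error(read_subject_csv(write_temp_series_csv(bad_cell)),
               "row 3.*twelve")

  dup <- t3
  dup$heart_rate_bpm[2] <- 98
  expect_error(read_subject_csv(write_temp_series_csv(dup)), "duplicate")

  inverted <- t3
  inverted$aortic_dia_mmHg[1] <- 200
  expect_error(read_subject_csv(write_temp_series_csv(inverted)),
               "systolic must exceed")

  one <- subject_series(t3[t3$heart_rate_bpm == 98, ])
  expect_equal(nrow(one), 1)
  expect_error(exercise_summary(one), "at least 2")
})

test_that("series are sorted by heart rate on construction", {
  t3 <- tibble::as_tibble(load_fixture("table3"))
  shuffled <- t3[c(5, 1, 9, 3, 2, 8, 4, 7, 6), ]
  s <- subject_series(shuffled)
  expect_equal(s$heart_rate_bpm, sort(t3$heart_rate_bpm))
})

test_that("brachial-to-aortic transform applies the fixed offsets", {
  expect_equal(brachial_to_aortic(120, 80),
               c(aortic_systolic = 122.25, aortic_diastolic = 74.55))
  expect_error(brachial_to_aortic(100, 100), "must exceed")
  expect_error(brachial_to_aortic(10, 3), "non-positive")

  # inverse chain reproduces the first record's printed pressures
  out <- brachial_to_aortic(144.75, 78.90)
  expect_equal(unname(out["aortic_systolic"]), 147.0)
  expect_equal(unname(out["aortic_diastolic"]), 73.45)
  expect_equal(aortic_to_ventricular_systolic(out[["aortic_systolic"]]), 152)
})

test_that("transform chain is affine and strictly monotone", {
  base <- brachial_to_aortic(120, 80)
  for (delta in c(0.5, 3, 17.25)) {
    shifted <- brachial_to_aortic(120 + delta, 80)
    expect_equal(shifted[["aortic_systolic"]] - base[["aortic_systolic"]],
                 delta)
    expect_equal(
      aortic_to_ventricular_systolic(shifted[["aortic_systolic"]]) -
        aortic_to_ventricular_systolic(base[["aortic_systolic"]]),
      delta)
  }
})

test_that("ventricular offset comes from config and defaults to 5 mmHg", {
  expect_equal(aortic_to_ventricular_systolic(147), 152)
  expect_equal(aortic_to_ventricular_systolic(181), 186)
  expect_error(aortic_to_ventricular_systolic(0), "> 0")
  cfg <- hemo_config(ventricular_offset_mmHg = 7)
  expect_equal(aortic_to_ventricular_systolic(147, config = cfg), 154)
  expect_error(hemo_config(not_a_key = 1), "unknown configuration")
})
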