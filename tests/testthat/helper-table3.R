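# Independent transcription of the packaged subject's printed measurements,
# used to check fixture integrity and as the oracle for chain computations.
table3_printed <- data.frame(
  heart_rate_bpm = c(98, 106, 114, 125, 136, 147, 153, 159, 169),
  ventricular_sys_mmHg = c(152, 158, 165, 169, 174, 178, 180, 182, 186),
  aortic_dia_mmHg = c(68, 65, 63, 63, 64, 65, 66, 67, 68),
  doppler_co_ml_min = c(11356, 12651, 14051, 15298, 16172, 17225, 17330,
                        17941, 18849),
  numerical_co_ml_min = c(10916.97, 12478.27, 14031.32, 15487.93, 16686.83,
                          18012.27, 18445.6, 18844.08, 19817.15)
)

table1_printed <- c(base_radius_mm = 11.5, commissure_radius_mm = 11.75,
                    valve_height_mm = 16.1, sinus_height_mm = 20.36,
                    leaflet_height_mm = 14, leaflet_free_edge_mm = 14.95,
                    sinus_max_radius_mm = 16.65, sinus_max_location_mm = 8.30,
                    leaflet_thickness_mm = 0.6)

table2_printed <- c(blood_viscosity_Pa_s = 3.5e-3, blood_density_kg_m3 = 1056,
                    leaflet_young_modulus_N_m2 = 6.885e6,
                    leaflet_poisson_ratio = 0.4999)

# Write a subject data frame to a temporary CSV and return the path.
write_temp_series_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path, na = "")
  path
}
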