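# Blood and leaflet material constants. Only density (and optionally
# viscosity) drive the reduced-order ejection model; the leaflet elastic
# constants are carried as metadata.
blood_viscosity_Pa_s: 3.5e-3
blood_density_kg_m3: 1056
leaflet_young_modulus_N_m2: 6.885e+6
leaflet_poisson_ratio: 0.4999
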