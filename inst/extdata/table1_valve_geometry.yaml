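# Parametric aortic-root/valve geometry (one-sixth wedge model), all mm.
base_radius_mm: 11.5
commissure_radius_mm: 11.75
valve_height_mm: 16.1
sinus_height_mm: 20.36
leaflet_height_mm: 14
leaflet_free_edge_mm: 14.95
sinus_max_radius_mm: 16.65
sinus_max_location_mm: 8.30
leaflet_thickness_mm: 0.6
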