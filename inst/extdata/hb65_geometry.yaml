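# HB 6.5 cancellous bone screw in a 3.2 mm pilot hole (foam bench values)
hole_diameter_mm: 3.2
major_diameter_mm: 6.5
shank_diameter_mm: 2.8
head_diameter_mm: 7.0
minor_diameter_mm: 3.0
half_angle_deg: 15
pitch_mm: 2.75
thread_length_mm: 30
mu_thread: 0.2
mu_head: 0.45
end_taper_deg: 60
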