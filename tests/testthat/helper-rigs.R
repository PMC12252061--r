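# Shared fixtures: an ideal-sensor rig (no noise, no quantization) and a
# deterministic material (no lot-to-lot variation).

ideal_rig <- function(...) {
  rig_spec(torque_noise_sd = 0, encoder_resolution_deg = 0,
           drawwire_resolution_mm = 0, ...)
}

fixed_material <- function(sigma = 4, name = "fix") {
  material_spec(name, sigma, strength_cv = 0)
}

# Geometry whose shank is wider than the thread root, so the stress
# concentration factor is defined (gamma > 0).
kt_geometry <- function(shank = 4, head = 12) {
  screw_geometry(shank_diameter = shank, head_diameter = head)
}
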