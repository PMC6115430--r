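# Reference configuration: extremely-low-birth-weight preterm patient under
# HFOV. Every field shown here equals the packaged default; an empty file
# yields the same configuration.
patient:
  body_mass: 0.76        # kg
  crs_total: 20.93       # ml/kPa, from single-occlusion ILFT
ventilator:
  frequency: 10          # Hz
  tidal_volume_per_kg: 2.0   # ml/kg
  ie_ratio: [1, 2]
  peep: 8 cmH2O
  fio2: 0.35
  n_cycles: 6
tube:
  inner_diameter: 3.0    # mm, uncuffed
  length: 100            # mm
leak:
  regime: linear
  resistance: 0.362      # kPa s/ml, calibrated to a 16% leak fraction
morphometry:
  trachea_length: 30     # mm, before dead-space calibration
  trachea_diameter: 4    # mm
  diameter_ratio: 0.79
  length_ratio: 0.79
target_deadspace_per_kg: 2.2   # ml/kg
extra_generations: 9           # lumped generations 8-16
seed: 1
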