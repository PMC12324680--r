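# Reference water-cooled Helmholtz coil design, as built.
# Units are explicit in the key names; keys not present fall back to
# package defaults.
coil:
  wire_diameter_mm: 0.71          # packing diameter of the 22 AWG magnet wire
  wire_conductor_diameter_mm: 0.6438  # bare copper diameter of 22 AWG
  wire_resistivity_ohm_m: 1.68e-8
  holder_inner_diameter_mm: 80
  winding_width_mm: 16
  n_turns: 96
  spacing_mm: 43.4                # centroid-to-centroid coil separation
operating:
  current_a: 1.0
  frequency_hz: 0
  toggle_time_ms: 130             # measured full on+off toggle
  drive_voltage_v: 2.75           # measured
  resistance_ohm: 2.74            # measured, series pair
  inductance_uh: 870              # measured
coolant:
  flow_lpm: 1.0
  inlet_temp_c: 30                # above the 28 C dew point at 37 C / 60 % RH
air:
  temp_c: 37
  relative_humidity_pct: 60
region:
  shape: cylinder                 # 35 mm culture dish with ~5 mm medium depth
  radius_mm: 17.5
  height_mm: 5
  axial_center_mm: 0
  grid_step_mm: 0.5
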