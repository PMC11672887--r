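id: lava
scenario: VALGIZATION
fragments:
- wall_tag: LATERAL_WALL
shift_mm: 2.5
angle_deg: 30.0
pressure_kPa: 1.2
contact_tol_mm: 1.0
drag_taper: 1.5
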