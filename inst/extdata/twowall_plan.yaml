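id: twowall
scenario: RESECTION
fragments:
- wall_tag: LATERAL_WALL
- wall_tag: FLOOR_WALL
pressure_kPa: 1.2
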