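# LAVA valgization vs two-wall resection on the default synthetic orbit
phantom: default
target_edge: 2.0
n_steps: 10
pitch: 0.5
seed: 1
plans:
- lava_plan.yaml
- twowall_plan.yaml
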