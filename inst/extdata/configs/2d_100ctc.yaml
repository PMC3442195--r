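name: 2d_100ctc
mode: no_flow_2d
u: 0.0
normalization: as_printed
seed: 20120914
rng_kind: Mersenne-Twister
sources:
  recipe:
    count: 100
    box: {x: [0.0, 600.0], "y": [0.0, 12.0]}
    strength: 1.0
    alpha: 1.5
times: [1.0, 5.0, 15.0, 500.0]
peak_times:
  log_range: [0.2, 500.0]
  n_points: 40
slices:
- {axis: "y", offset: 0.0}
- {axis: "y", offset: 150.0}
- {axis: "y", offset: 300.0}
grid: {x: [0.0, 600.0], "y": [0.0, 300.0], nx: 256, ny: 256}
profile_points: 1201
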