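name: 3d_trackers
mode: constant_flow_3d
u: 0.1
normalization: as_printed
seed: 20120914
rng_kind: Mersenne-Twister
sources:
  recipe:
    count: 100
    box: {x: [0.0, 600.0], "y": [0.0, 600.0], z: [0.0, 20.0]}
    strength: 1.0
    alpha: 1.5
times: [8.0, 46.0, 99.0, 167.0, 220.0]
slices:
- {axis: "z", offset: 0.0}
- {axis: "z", offset: 10.0}
- {axis: "z", offset: 20.0}
grid: {x: [0.0, 650.0], "y": [0.0, 650.0], nx: 128, ny: 128}
profile_points: 1201
trackers:
  n_high: 200
  n_low: 200
  box: {x: [0.0, 600.0], "y": [0.0, 600.0], z: [0.0, 20.0]}
  eps: 2.0
  seed: 77
  t0: 1.0
  t1: 220.0
  dt: 1.0
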