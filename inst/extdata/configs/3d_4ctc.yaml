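name: 3d_4ctc
mode: constant_flow_3d
u: 1.0
normalization: as_printed
seed: 20120914
rng_kind: Mersenne-Twister
sources:
  explicit:
  - {x0: 300.0, y0: 300.0, z0: 45.0, strength: 1.0, alpha: 1.5}
  - {x0: 180.0, y0: 400.0, z0: 30.0, strength: 1.0, alpha: 1.5}
  - {x0: 300.0, y0: 100.0, z0: 30.0, strength: 1.0, alpha: 1.5}
  - {x0: 275.0, y0: 200.0, z0: 60.0, strength: 1.0, alpha: 1.5}
times: [1.0, 10.0, 40.0, 75.0]
slices:
- {axis: "z", offset: 0.0}
- {axis: "z", offset: 45.0}
- {axis: "z", offset: 90.0}
grid: {x: [0.0, 700.0], "y": [0.0, 500.0], nx: 256, ny: 256}
profile_points: 1201
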