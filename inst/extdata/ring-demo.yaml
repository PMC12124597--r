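# Scaled-down 2D ring-array demonstration: sparse 64-element ring,
# three-disk phantom, UBP reconstruction, subset-coherence prior, and
# regularized refinement.
grid:
  shape: [128, 128]
  spacing: 2.0e-4          # 0.2 mm -> 25.6 mm field of view
geometry:
  type: ring
  n_elements: 64
  radius: 0.05             # 5 cm
acquisition:
  sound_speed: 1500.0
  sampling_rate: 7.5e+6    # bin width c/fs matches the grid spacing
  n_samples: 512
  t0: 0.0
phantom:
  type: disks
  disks:
    - {center: [-0.004, 0.003], radius: 0.0025, amplitude: 1.0}
    - {center: [0.005, -0.002], radius: 0.0015, amplitude: 0.8}
    - {center: [0.000, -0.006], radius: 0.0010, amplitude: 0.6}
prior:
  algo: ubp
  s: 8
  k: 30
  seed: 11
# refinement weights, step size and iteration count of the 2D ring study
risp:
  lambda_con: 0.2
  lambda_reg: 0.8
  learning_rate: 0.001
  num_iters: 150
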