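# Default study configuration: geometry of the four task variants, noise,
# cohort structure and sampler settings. All numeric defaults live here.
# Coordinates are abstract data-plane units, y increasing upward; shape_a
# is the canonical "up" shape, shape_b the canonical "down" shape, and
# mirror randomization swaps them per trial.
#
# The per-variant sigma values were produced by calibrate_difficulty()
# (target: a one-percentage-point generative accuracy advantage of an
# exact-Bayes observer over a maximum-likelihood observer; seed 20260920,
# budget 120000 trials per evaluation).
seed: 20260920
noise:
  n_obs: 10
mirror_randomization: true
block_size: 100
variants:
  dimensionality:
    sigma: 1.201114
    shape_a: {kind: point, location: [0.0, 0.5]}
    shape_b: {kind: segment, from: [-1.0, -0.5], to: [1.0, -0.5]}
  boundary:
    sigma: 1.607213
    shape_a: {kind: segment, from: [-2.0, 0.5], to: [0.0, 0.5]}
    shape_b: {kind: segment, from: [0.0, -0.5], to: [2.0, -0.5]}
  volume:
    sigma: 1.152164
    shape_a: {kind: segment, from: [-0.25, 0.5], to: [0.25, 0.5]}
    shape_b: {kind: segment, from: [-2.0, -0.5], to: [2.0, -0.5]}
  robustness:
    sigma: 0.567972
    shape_a: {kind: segment, from: [-1.0, 0.5], to: [1.0, 0.5]}
    shape_b: {kind: arc, center: [0.0, 0.0], radius: 0.5,
              theta0: -3.5707963267948966, span: 4.0, orientation: 1}
cohort:
  n_participants: 50
  n_trials: 500
calibration:
  target_gap: 0.01
  budget: 40000
  sigma_range: [0.15, 3.0]
  tol: 0.0015
sampler:
  chains: 4
  warmup: 1000
  iter: 1000
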