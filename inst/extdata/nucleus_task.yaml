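# Reference nucleus-segmentation optimisation task.
# Search space of the reference pipeline's tunable settings: each one is
# declared explicitly with minimum, maximum and interval.
search_space:
  - name: Size of adaptive window
    kind: integer
    min: 17
    max: 97
    interval: 8
  - name: Threshold correction factor I
    kind: float
    min: 0.6
    max: 2.0
    interval: 0.1
  - name: Typical artifact diameter
    kind: float
    min: 0.0
    max: 15.0
    interval: 1.0
  - name: Threshold correction factor II
    kind: float
    min: 0.6
    max: 1.5
    interval: 0.1

# Stopping: optimisation ends when the current quality score reaches the
# target, or after max_iterations proposals beyond the bootstrap.
target_qs: 9
max_iterations: 30
bootstrap_count: 2
seed: 1

# auto | manual | composite
evaluator: manual
weights:
  automated: 0.5
  manual: 0.5

# Tolerance-range criteria for the automated evaluator (at most 4).
# Well-segmented nuclei are convex and compact, so high solidity and a
# plausible area range characterise them.
criteria:
  - object: primary
    measurement: solidity
    min: 0.9
  - object: primary
    measurement: area
    min: 80
    max: 900

# Acquisition and surrogate settings.
xi: 0.5
candidate_count: 2048
gp_bounds:
  sigma_n: [1.0e-6, 4.0]
  sigma_f: [1.0e-3, 100.0]
  sigma_l: [1.0e-3, 10.0]
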