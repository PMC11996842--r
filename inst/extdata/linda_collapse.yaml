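# Example scenario: three-state Linda collapse model.
# Strict orderings are enforced: lam decreasing (strongest alignment for F),
# gamma increasing (fastest decay for BT).
kind: linda_collapse
labels: ["F", "F&BT", "BT"]
lam: [1.0, 0.6, 0.3]
gamma: [0.05, 0.15, 0.4]
a0_magnitude: [0.7071067811865476, 0.0, 0.7071067811865476]
a0_phase: [0.0, 0.0, 0.0]
t_max: 6
n_steps: 121
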