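# Desk-scale surface-recovery experiment (see ?experiment_config)
truth_kind: cortical
model_kind: matched
position: constrained
n_sources: 10
true_extents: [0, 3, 6, 9, 12, 15, 18]
Q: 20
radii: [0, 2, 4, 6, 8, 10, 12, 14, 16, 18, 20]
n_seeds: 3
shifts: [0]
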