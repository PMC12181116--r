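# Default study conditions for the before/after metric-learning
# delta-response experiment: weak-connectivity sheet (U = 0.1, disc radius
# R = 1) on a 64 x 64 grid, probed at the stimulus site.
U: 0.1
R: 1.0
lapU: 0.0
nx: 64
ny: 64
dx: 0.1
dt: 0.05
n_steps: 400
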