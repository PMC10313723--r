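# Train the full (library + delay-kernel) closure on four (Nx, Re) pairs,
# then evaluate the 35-cell generalization sweep.
experiment: burgers_sweep
dt_data: 0.02
t_train: 2.0
seeds: [25]
epochs: 6
steps_per_epoch: 5
batch_time: 0.05
lr: 0.03
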