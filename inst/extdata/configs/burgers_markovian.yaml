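# Truncation-error discovery for the under-resolved Burgers solver.
# Training pairs (Nx, Re) as in the full study; reduce dt_data / epochs
# for quick runs.
experiment: burgers_markovian
dt_data: 0.01
t_train: 4.0
seeds: [21, 22, 23]
epochs: 20
lr: 0.05
batch_time: 0.05
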