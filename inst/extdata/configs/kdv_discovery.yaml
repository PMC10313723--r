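# Two-soliton term discovery: recover dispersion (-u_xxx) and the missing
# advection share (-5 u u_x) from a redundant library, starting from the
# advection-only low-fidelity model.
experiment: kdv_discovery
n_x: 200
dt_data: 0.01      # snapshot interval of the analytic truth
t_train: 1.0       # training horizon
t_val: 1.25        # validation horizon (continuation solve)
seeds: [11, 12, 13]
epochs: 60
lr: 0.06
lr_decay: 0.95
batch_time: 0.01
l1: 1.0e-4
l2: 1.0e-5
prune_threshold: 0.05
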