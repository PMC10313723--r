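# Augment the aggregated NPZ-OA column with mortality library + memory
# kernel (staged training; year-long forecast appended to the result).
experiment: oa_complexity
t_data: 60
t_truth: 120
dt_data: 0.1
seeds: [41, 42, 43]
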