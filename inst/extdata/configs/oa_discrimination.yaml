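# Zooplankton-mortality law discrimination in the NPZD-OA column.
experiment: oa_discrimination
t_data: 30
dt_data: 0.1
seeds: [31, 32, 33]
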