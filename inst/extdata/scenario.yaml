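# Example scenario configuration for the command-line runner.
perspectives: [healthcare, societal]
outcomes: [weekly, binge]
n_reps: 5000
seed: 1
outlier_threshold: 5000
include_substance_costs: true
wtp_max: 1000
wtp_step: 10
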