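# Example run configuration: the standard task (probabilities may be given
# as decimals or fraction strings).
n_levers: 3
block_length: 24
blocks_per_session: 12
n_sessions: 4
low_risk_target: 7/8
low_risk_other: 1/16
high_risk_target: 5/8
high_risk_other: 3/16
model: fql
seed: 1
n_reps: 100
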