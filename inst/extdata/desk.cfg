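# Reduced desk-scale grid: a contrast-rich scenario subset at 200
# replicates, CS structure only.
n_clusters: 12
subjects_per_cluster: 20
scenarios: [D1, D9, D17, D27]
formulations: [M4, M6, M7, M9]
structures: [CS]
n_reps: 200
master_seed: 20181213
level: 0.95
ci_reference: normal
mse_mode: conditional
output: grid_desk.csv
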