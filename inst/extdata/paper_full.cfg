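# Full-scale replicate grid: every scenario x formulation x structure cell
# at 1000 replicates.  This is a long batch run, not a desk-scale job.
n_clusters: 12
subjects_per_cluster: 20
scenarios: all
formulations: all
structures: [CS, AR1]
n_reps: 1000
master_seed: 20181213
level: 0.95
ci_reference: normal
mse_mode: conditional
output: grid_full.csv
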