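# Demo configuration for the end-to-end pipeline:
#   Rscript inst/cli/engagetraj.R run-all --config inst/extdata/demo_config.yaml --out demo_run
seed: 1
n_users: 82
n_tau: 84
n_days: 155
k_min: 2
k_max: 4
n_restarts: 100
min_cluster_size: 0.15
n_resamples: 100
resample_frac: 0.8
comparison: both
p_adjust: false
plots: true
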