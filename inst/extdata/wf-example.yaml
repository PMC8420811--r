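# Weber-noise Monte Carlo over the five standard launch distances.
# Run with: Rscript inst/cli/ttcgs-cli.R --config inst/extdata/wf-example.yaml
analysis: wf
z_init: [15, 20, 30, 40, 50]
flight_time: 2
n_sims: 10000
k_theta: 0.05
k_gamma: 0.05
k_gamma_dot: 0.05
seed: 1
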