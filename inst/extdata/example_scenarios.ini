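# Example scenario grid: one section per Monte Carlo cell.
# Keys override sim_config() defaults (n0=n1=10, s0=15, n_genes=1000).

[normal_null_r1]
distribution = normal
md = 0
r = 1
reps = 5000

[normal_md10_r2]
distribution = normal
md = 10
r = 2
reps = 5000
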