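# Base (no AKI/DEATH covariates) population model, cooled (TH) cohort.
pna50                 2.31
gfrss_gfr0            1.78
ksyn_gfr0             0.654
gamma                 5.26
k                     0.709
pna_p                 2.42
qmax_uf               0.575
ga_slope_pna_p        -0.0747
ga_slope_qmax_uf      0.0178
ga_center             34.2
omega2_pna50          0.413
omega2_gfrss_gfr0     0.107
omega2_ksyn_gfr0      0.0233
omega2_gamma          0.435
omega2_k              0.207
omega2_pna_p          0.11
omega2_qmax_uf        0.153
sigma2                0.0218
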