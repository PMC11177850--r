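# Final population model, cooled (TH) neonate cohort.
# Typical values; back-flow block fixed at reference-population values.
pna50_aki0            1.94
pna50_aki1            6.21
gfrss_gfr0            1.74
ksyn_gfr0_aki0_death0 0.631
ksyn_gfr0_aki1_death0 0.785
ksyn_gfr0_aki0_death1 0.750
ksyn_gfr0_aki1_death1 0.834
gamma_aki0            4.46
gamma_aki1            22.8
k                     0.709
pna_p                 2.42
qmax_uf               0.575
ga_slope_pna_p        -0.0747
ga_slope_qmax_uf      0.0178
ga_center             34.2
# Between-subject variances (log scale)
omega2_pna50          0.220
omega2_gfrss_gfr0     0.0955
omega2_ksyn_gfr0      0.0180
omega2_gamma          0.168
omega2_k              0.207
omega2_pna_p          0.11
omega2_qmax_uf        0.153
# Residual variance of log sCr
sigma2                0.0227
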