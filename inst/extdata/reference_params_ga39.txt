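# Reference (non-asphyxiated) neonate population model.
# Maturation parameters are the printed typical values for GA = 39 weeks;
# back-flow block at the GA reference with its GA slopes.
# Between-subject variances of the maturation parameters and the residual
# variance are not part of this packaged table (set to 0): intended for
# typical-curve simulation, not for estimation.
pna50                 18.2
gfrss_gfr0            2.01
ksyn_gfr0             0.394
gamma                 3.57
k                     0.709
pna_p                 2.42
qmax_uf               0.575
ga_slope_pna_p        -0.0747
ga_slope_qmax_uf      0.0178
ga_center             34.2
omega2_pna50          0
omega2_gfrss_gfr0     0
omega2_ksyn_gfr0      0
omega2_gamma          0
omega2_k              0.207
omega2_pna_p          0.11
omega2_qmax_uf        0.153
sigma2                0
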