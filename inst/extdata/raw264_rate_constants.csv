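name,value,sem
kf1,1.30e+01,1.01e-02
kf2,5.62e-02,1.30e-02
kf3,1.11e-03,3.20e-03
kf4,1.49e-04,1.11e-03
kf5,1.61e-02,8.38e-04
kf6,5.28e-01,1.83e-02
kf7,1.81e-02,2.71e-03
kf8,2.99e-01,3.25e-02
kf9,1.15e-01,6.85e-03
kb9,1.7176,5.47e-03
kf10,3.88e-01,1.02e-02
kb10,8.63e-01,1.23e-02
kf11,1.07e-01,5.62e-03
kf12,2.49e-02,3.01e-03
kf13,5.00e-05,7.20e-06
kf14,8.25e-02,6.57e-03
kf15,9.07e-03,9.56e-03
kf16,8.03e-01,1.39e-02
kf17,1.29e-04,7.64e-06
kf18,1.12e-01,4.05e-03
kf19,6.50e-02,3.13e-02
kb19,4.72e-02,8.67e-03
kf20,4.48e-01,2.50e-02
kb20,1.3343,2.52e-02
kf21,1.91e-05,1.98e-02
kf22,9.79e-03,1.28e-03
kf23,0.00e+00,2.55e-03
kf24,2.39e-02,3.05e-03
kf25,4.58e-03,3.43e-03
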