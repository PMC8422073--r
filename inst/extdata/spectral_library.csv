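# Reference absorption spectra on the 700-960 nm / 10 nm grid, literature-shaped compilation.
# Hb/HbO2: molar-extinction shapes converted to whole-blood absorption (150 g/l haemoglobin), cm^-1.
# H2O: pure-water absorption, cm^-1. Lipid: mammalian-fat shape, 930 nm peak, cm^-1.
# ICG: plasma spectrum (~6.5 uM), 800 nm peak, cm^-1. Only relative shape matters for unmixing in a.u.
wavelength_nm,Hb,HbO2,Lipid,H2O,ICG
700,9.607,1.553,0.012,0.0060,1.250
710,9.071,1.682,0.011,0.0074,1.400
720,8.434,1.864,0.011,0.0104,1.600
730,7.840,2.088,0.012,0.0170,1.900
740,7.406,2.388,0.012,0.0236,2.250
750,7.524,2.774,0.011,0.0260,2.700
760,8.290,3.138,0.011,0.0270,3.250
770,7.021,3.481,0.012,0.0250,3.900
780,5.762,3.802,0.012,0.0236,4.500
790,4.712,4.145,0.013,0.0227,4.850
800,4.204,4.370,0.014,0.0224,5.000
810,3.845,4.627,0.015,0.0239,4.900
820,3.716,4.820,0.017,0.0279,4.500
830,3.599,5.055,0.021,0.0300,3.850
840,3.534,5.248,0.025,0.0346,3.100
850,3.481,5.666,0.029,0.0434,2.350
860,3.449,5.816,0.032,0.0470,1.700
870,3.427,5.944,0.035,0.0510,1.200
880,3.416,6.051,0.040,0.0551,0.800
890,3.427,6.212,0.050,0.0600,0.550
900,3.470,6.415,0.070,0.0679,0.350
910,3.481,6.480,0.100,0.0781,0.250
920,3.491,6.523,0.200,0.1080,0.175
930,3.502,6.544,0.280,0.1370,0.125
940,3.513,6.555,0.180,0.2680,0.090
950,3.524,6.533,0.110,0.3900,0.065
960,3.534,6.501,0.090,0.4200,0.050
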