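class,center,fwhm,amplitude,shape
radix_bupleuri,3300,300,0.28,lorentzian
radix_bupleuri,2920,70,0.14,lorentzian
radix_bupleuri,1780,14,0.12,lorentzian
radix_bupleuri,1730,16,0.22,lorentzian
radix_bupleuri,1650,90,0.18,lorentzian
radix_bupleuri,1600,14,0.15,lorentzian
radix_bupleuri,1540,14,0.17,lorentzian
radix_bupleuri,1505,12,0.12,lorentzian
radix_bupleuri,1460,16,0.22,lorentzian
radix_bupleuri,1400,90,0.12,lorentzian
radix_bupleuri,1355,14,0.19,lorentzian
radix_bupleuri,1315,12,0.12,lorentzian
radix_bupleuri,1240,18,0.26,lorentzian
radix_bupleuri,1155,14,0.3,lorentzian
radix_bupleuri,1100,70,0.3,lorentzian
radix_bupleuri,1030,50,0.38,lorentzian
radix_bupleuri,995,12,0.24,lorentzian
radix_bupleuri,955,12,0.17,lorentzian
radix_bupleuri,895,10,0.12,lorentzian
radix_bupleuri,860,12,0.12,lorentzian
radix_bupleuri,815,12,0.09,lorentzian
radix_bupleuri,765,14,0.15,lorentzian
radix_bupleuri,705,12,0.12,lorentzian
b_smithii,3300,300,0.2604,lorentzian
b_smithii,2920,70,0.1512,lorentzian
b_smithii,1780,14,0.1092,lorentzian
b_smithii,1730,16,0.1958,lorentzian
b_smithii,1650,90,0.162,lorentzian
b_smithii,1600,14,0.1365,lorentzian
b_smithii,1540,14,0.1513,lorentzian
b_smithii,1505,12,0.1308,lorentzian
b_smithii,1460,16,0.2442,lorentzian
b_smithii,1400,90,0.132,lorentzian
b_smithii,1355,14,0.2071,lorentzian
b_smithii,1315,12,0.1332,lorentzian
b_smithii,1240,18,0.286,lorentzian
b_smithii,1155,14,0.327,lorentzian
b_smithii,1100,70,0.27,lorentzian
b_smithii,1030,50,0.3382,lorentzian
b_smithii,995,12,0.2184,lorentzian
b_smithii,955,12,0.1513,lorentzian
b_smithii,895,10,0.108,lorentzian
b_smithii,860,12,0.1092,lorentzian
b_smithii,815,12,0.0801,lorentzian
b_smithii,765,14,0.135,lorentzian
b_smithii,705,12,0.1092,lorentzian
b_bicaule,3300,300,0.2996,lorentzian
b_bicaule,2920,70,0.1316,lorentzian
b_bicaule,1780,14,0.1308,lorentzian
b_bicaule,1730,16,0.2442,lorentzian
b_bicaule,1650,90,0.198,lorentzian
b_bicaule,1600,14,0.1635,lorentzian
b_bicaule,1540,14,0.1887,lorentzian
b_bicaule,1505,12,0.1092,lorentzian
b_bicaule,1460,16,0.1958,lorentzian
b_bicaule,1400,90,0.108,lorentzian
b_bicaule,1355,14,0.1729,lorentzian
b_bicaule,1315,12,0.1068,lorentzian
b_bicaule,1240,18,0.234,lorentzian
b_bicaule,1155,14,0.273,lorentzian
b_bicaule,1100,70,0.33,lorentzian
b_bicaule,1030,50,0.4218,lorentzian
b_bicaule,995,12,0.2616,lorentzian
b_bicaule,955,12,0.1887,lorentzian
b_bicaule,895,10,0.132,lorentzian
b_bicaule,860,12,0.1308,lorentzian
b_bicaule,815,12,0.0999,lorentzian
b_bicaule,765,14,0.165,lorentzian
b_bicaule,705,12,0.1308,lorentzian
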