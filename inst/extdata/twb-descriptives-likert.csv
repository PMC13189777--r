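factor,men_mean,men_sd,women_mean,women_sd
diet1,2.56,1.61,3.28,1.62
diet2,2.82,1.25,2.98,1.32
diet3,2.49,0.98,2.63,1.03
diet4,3.73,1.25,4.13,1.08
diet5,3.87,0.91,4.05,0.85
diet6,4.40,0.95,4.42,0.93
diet7,3.69,1.21,3.87,1.14
diet8,4.29,0.73,4.37,0.68
diet9,3.36,1.46,3.21,1.44
diet10,2.79,1.43,2.63,1.45
diet11,3.54,1.61,3.34,1.64
diet12,3.45,1.63,3.58,1.61
diet13,3.33,1.47,3.21,1.51
diet14,3.22,1.56,2.79,1.59
diet15,3.35,1.42,3.02,1.44
diet16,1.63,0.94,1.68,0.99
diet17,3.64,1.57,3.31,1.67
education,5.75,0.87,5.45,0.96
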