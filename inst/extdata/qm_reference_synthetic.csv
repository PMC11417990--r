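"series","pair","qm_energy","target_epsilon"
"pipi","F-F",-2.665,0.49
"pipi","F-Y",-2.6605,0.463
"pipi","F-W",-2.8285,0.531
"pipi","Y-Y",-2.58272,0.43792
"pipi","Y-W",-2.73392,0.50112
"pipi","W-W",-3.02712,0.57632
"cation_pi","R-F",-2.183,0.471
"cation_pi","R-Y",-2.1672,0.4424
"cation_pi","R-W",-2.3232,0.5144
"pipi_query","H0-H0",-2.715,NA
"cation_pi_query","H0-R",-2.213,NA
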