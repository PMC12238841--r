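allele	frequency
HLA-A*01:01	0.170
HLA-A*02:01	0.270
HLA-A*02:06	0.030
HLA-A*03:01	0.130
HLA-A*11:01	0.090
HLA-A*24:02	0.170
HLA-B*07:02	0.090
HLA-B*08:01	0.080
HLA-B*15:01	0.050
HLA-B*35:01	0.060
HLA-B*40:01	0.050
HLA-B*44:02	0.060
HLA-B*44:03	0.040
HLA-B*51:01	0.060
HLA-C*01:02	0.050
HLA-C*03:04	0.070
HLA-C*04:01	0.120
HLA-C*06:02	0.090
HLA-C*07:01	0.120
HLA-C*07:02	0.130
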