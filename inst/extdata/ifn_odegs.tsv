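gene	p_observed	p_erex	p_grex	odeg_rank
OAS1	1.25e-04	1.25e-04	6.76e-01	1
MX1	2.50e-04	2.37e-03	1.50e-02	2
ADAR	5.00e-04	3.75e-04	5.97e-01	7
IRF7	1.12e-03	1.50e-03	2.74e-02	16
ISG15	1.62e-03	1.62e-03	4.89e-01	20
IFIT1	2.00e-03	1.87e-03	8.29e-02	21
IFI35	6.88e-03	1.24e-02	1.10e-01	62
MX2	1.05e-02	1.01e-02	4.92e-01	88
OASL	1.25e-02	2.95e-02	1.54e-01	104
IFNAR2	3.84e-02	2.76e-02	9.12e-01	292
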