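# Built-in cluster profiles in the plain-text definition format
# NAME<TAB>cluster1-cluster2-...-clusterK
CP20	A-C-D-E-F-G-H-I-K-L-M-N-P-Q-R-S-T-V-W-Y
CP13	G-IV-FYW-A-L-M-E-QRK-P-ND-HS-T-C
CP11	G-IV-FYW-A-LM-EQRK-P-ND-HS-T-C
CP9	G-IV-FYW-ALM-EQRK-P-ND-HS-TC
CP8	G-IV-FYW-ALM-EQRK-P-ND-HSTC
CP5	G-IVFYW-ALMEQRK-P-NDHSTC
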