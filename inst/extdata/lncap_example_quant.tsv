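# Example Spectrum Mill protein quantification: four glycoproteins from
# androgen-treated LNCaP cells (total abundance after BSA spike-in
# normalization), vehicle plus three R1881 doses.
protein_id	0nM	0.1nM	1.0nM	10nM
PRKDC	3.72e7	2.71e7	3.29e7	2.44e7
GAPDH	9.66e7	9.03e7	2.48e7	3.06e7
ATP1B1	8.18e6	4.97e6	1.40e7	2.86e5
CLTC	2.99e8	1.93e8	1.95e8	1.43e8
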