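pop	allele_count	allele_total
Yao	18	124
Miao	2	20
She	0	20
Dai	1	18
Han	2	80
Tibetan	0	76
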