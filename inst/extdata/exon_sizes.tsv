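gene	exon1	exon2	exon3	exon4	exon5	exon6	exon7	exon8	exon9	exon10	exon11	exon12	exon13	exon14	aa_homology
gamma-PLE	52	208	145	134	154	105	105	39	141	81	148	132	73	181	NA
PLE-1	52	208	145	134	154	105	105	39	141	81	148	132	73	181	99
PLE-B9	52	208	145	134	154	105	105	39	141	81	148	132	73	181	96
PLE-C4	52	208	145	134	154	105	105	39	141	81	148	132	73	181	96
PLE-G2	52	208	145	134	154	105	105	39	141	81	148	132	73	181	98
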