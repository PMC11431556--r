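exposure	mediator	outcome	mediated	ci_low	ci_high	proportion_pct	p_reported
CCR2 on CD62L+ plasmacytoid DC	3-hydroxyhexanoate levels	HCC	0.0131	0.0024	0.0238	9.03	0.0166
CCR2 on CD62L+ plasmacytoid DC	Dodecenedioate (C12:1-DC) levels	HCC	0.0132	0.0033	0.0232	9.14	0.0093
CD3- lymphocyte %leukocyte	X-24811 levels	HCC	0.0128	0.0018	0.0239	7.04	0.0232
CD4 on TD CD4+	9,10-DiHOME levels	HCC	-0.00596	-0.0108	-0.0011	4.73	0.0154
CD4 on TD CD4+	X-24306 levels	HCC	-0.00844	-0.0169	-2.2e-5	6.71	0.0494
CD4 on TD CD4+	X-24307 levels	HCC	-0.0188	-0.0335	-0.0040	14.9	0.0126
CD14 on Mo MDSC	Linolenate [a or g; (18:3n3 or 6)] levels	HCC	-0.0128	-0.0247	-0.0009	10.4	0.0339
CD19 on PB/PC	Linolenate [a or g; (18:3n3 or 6)] levels	HCC	0.0389	0.012	0.0658	19.3	0.0046
CD19 on unsw mem	N-acetyl-isoputreanine levels	HCC	-0.00829	-0.0163	-0.0002	4.27	0.0434
CD24 on IgD+ CD38-	3-methyl-2-oxovalerate to 4-methyl-2-oxopentanoate ratio	HCC	-0.00862	-0.0162	-0.0010	6.08	0.0262
CD28- CD25++ CD8br %CD8br	5alpha-pregnan-3beta,20beta-diol monosulfate (1) levels	HCC	0.00593	-0.0002	0.0121	3.21	0.0579
CD28- CD25++ CD8br %CD8br	N-acetyl-isoputreanine levels	HCC	0.00745	-0.0001	0.015	4.03	0.0538
CD64 on CD14- CD16+ monocyte	Citrate to 4-hydroxyphenylpyruvate ratio	HCC	0.0327	0.0045	0.0607	12	0.0226
Granulocyte AC	Serotonin levels	HCC	-0.0155	-0.0288	-0.0022	9.96	0.0221
HLA DR on HLA DR+ CD8br	Phenyllactate levels	HCC	-0.014	-0.0281	0.0001	6.7	0.0523
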