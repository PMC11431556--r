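label	or	or_low	or_high	p_reported
3-phosphoglycerate-to-glycerate ratio	1.901	1.215	2.972	0.005
Taurochenodeoxycholate levels	1.747	1.098	2.780	0.019
X-24307 levels	0.622	0.411	0.942	0.025
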