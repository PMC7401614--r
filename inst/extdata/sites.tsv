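site_id	zone	location	precipitation_mm
BZ	humid	Bizerte	800-1200
BA1	semi_arid	Bou Argoub	400-600
BA2	semi_arid	Bou Argoub	400-600
BA3	semi_arid	Bou Argoub	400-600
KA1	semi_arid	Kairouan	400-600
KA2	semi_arid	Kairouan	400-600
KA3	semi_arid	Kairouan	400-600
KS1	upper_arid	Kasserin	200-400
KS2	upper_arid	Kasserin	200-400
KS3	upper_arid	Kasserin	200-400
KS4	upper_arid	Kasserin	200-400
KS5	upper_arid	Kasserin	200-400
KS6	upper_arid	Kasserin	200-400
SB1	upper_arid	Sidi Bouzid	200-400
SB2	upper_arid	Sidi Bouzid	200-400
SB3	upper_arid	Sidi Bouzid	200-400
GF1	lower_arid	Gafsa	100-200
GF2	lower_arid	Gafsa	100-200
GF3	lower_arid	Gafsa	100-200
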