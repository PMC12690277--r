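pair_id	anchor_text	antithesis_text	source	domain_tag
mpq_cramping	My pain is cramping	My pain is relaxing	MPQ	sensory
mpq_splitting	My pain is splitting	My pain is light and dull	MPQ	sensory
mpq_throbbing	My pain is throbbing	My pain is steady	MPQ	sensory
mpq_stabbing	My pain is stabbing	My pain is dull and aching	MPQ	sensory
mpq_tiring	My pain is tiring-exhausting	My pain is bearable	MPQ	affective
painvar_in_pain	I am in pain	I have no pain	pain_variability	intensity
promis_focus	I am unable to focus	I am able to focus	PROMIS	pain_interference
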