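Lagenia_demo_a	lagenocarps
Lagenia_demo_b	lagenocarps
Trigona_demo_a	trigonocarps
Trigona_demo_b	trigonocarps
Trigona_demo_c	trigonocarps
Cardia_demo_a	cardiocarps
Cardia_demo_b	cardiocarps
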