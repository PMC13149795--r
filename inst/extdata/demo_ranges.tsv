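Protosperma_demo	365	358
Lagenia_demo_a	355	345
Lagenia_demo_b	350	340
Trigona_demo_a	335	325
Trigona_demo_b	330	318
Trigona_demo_c	320	310
Cardia_demo_a	315	300
Cardia_demo_b	305	298
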