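#NEXUS
[ Synthetic demonstration matrix: 8 invented fossil-seed taxa x 12
  unordered characters, with unknown (?), inapplicable (-) and
  polymorphic ({}) cells.  Not real data. ]
BEGIN DATA;
  DIMENSIONS NTAX=8 NCHAR=12;
  FORMAT SYMBOLS="0 1 2" MISSING=? GAP=-;
  MATRIX
    Protosperma_demo   00000000-{01}00
    Lagenia_demo_a     1100001?0000
    Lagenia_demo_b     110000210000
    Trigona_demo_a     101001011100
    Trigona_demo_b     1010111?1100
    Trigona_demo_c     101011211100
    Cardia_demo_a      100101000100
    Cardia_demo_b      100101100110
  ;
END;
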