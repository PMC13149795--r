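1	architectural
2	architectural
3	architectural
4	wall_structure
5	wall_structure
6	external_topography
7	external_topography
8	cellular
9	cellular
10	pollination
11	pollination
12	pollination
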