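# Synthetic consensus-derived example matrix for the 16-bp CTCF core motif
# (CCASYAGRKGGCRSYG-like). Columns: A C G T, one row per motif position.
0.05 0.85 0.05 0.05
0.05 0.85 0.05 0.05
0.85 0.05 0.05 0.05
0.05 0.45 0.45 0.05
0.05 0.45 0.05 0.45
0.85 0.05 0.05 0.05
0.05 0.05 0.85 0.05
0.45 0.05 0.45 0.05
0.05 0.05 0.45 0.45
0.05 0.05 0.85 0.05
0.05 0.05 0.85 0.05
0.05 0.85 0.05 0.05
0.45 0.05 0.45 0.05
0.05 0.45 0.45 0.05
0.05 0.45 0.05 0.45
0.05 0.05 0.85 0.05
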