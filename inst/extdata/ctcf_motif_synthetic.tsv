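# Synthetic CTCF-like position count matrix (14 bp core, consensus
# CCACCAGGTGGCAG). Rows A, C, G, T; counts out of 100 sequences. This is a
# constructed stand-in motif for scanning the synthetic region, not a
# database-derived CTCF matrix.
A	5	8	70	6	5	75	4	3	5	4	6	5	80	6
C	80	78	10	82	85	8	5	4	5	6	8	82	6	5
G	8	6	12	6	5	10	86	88	8	84	80	7	8	84
T	7	8	8	6	5	7	5	5	82	6	6	6	6	5
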