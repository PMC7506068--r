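label	n_orfs	total_length_bp	printed_average_length	printed_pct_complete
RGC	2662347	1546177902	580.76	63.99
HGC	1889968	1094992671	579.37	40.29
POGC	1742331	1077159972	618.23	60.72
PDGC	1375491	681415047	495.40	98.86
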