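metric	count	printed_pct
rgc_orfs	2662347	NA
rgc_bacteria_classified	1551890	58.29
rgc_archaea_classified	187348	7.04
orfs_unmapped_by_reads	309605	NA
orfs_unmapped_pdgc_only	228478	73.8
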