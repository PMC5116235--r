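# disease panels: number of genes analysed per disease after excluding
# poorly covered genes, and the largest per-gene case count
disease	genes_tested	n_cases_max
HCM	20	6179
DCM	46	1315
ARVC	8	361
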