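# component clinical cardiomyopathy cohorts by referring laboratory
# OMGL = Oxford Medical Genetics Laboratory, LMM = Laboratory for Molecular
# Medicine; n_cases = maximum number of cases sequenced for that disease
disease	laboratory	n_cases
HCM	OMGL	3267
HCM	LMM	2912
DCM	OMGL	559
DCM	LMM	756
ARVC	OMGL	361
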