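disease	group	RR	HR	SIR	protective
Asthma	inflammatory		1.36		FALSE
Alzheimer's disease	inflammatory				TRUE
Psoriasis	inflammatory	1.21			FALSE
Irritable bowel syndrome	inflammatory				TRUE
Rheumatoid arthritis	inflammatory			1.20	FALSE
Ulcerative colitis	inflammatory	2.4		2.4	FALSE
Crohn's disease	inflammatory	2.5			FALSE
Non-alcoholic steatohepatitis	inflammatory		7.62		FALSE
Hepatitis B virus	inflammatory		15.77		FALSE
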