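partner	call
Vps21	periodic
Ypt6	periodic
Ypt31	periodic
Sec4	aperiodic
Ypt1	aperiodic
Ypt7	aperiodic
Ypt10	aperiodic
Ypt32	aperiodic
Ypt52	aperiodic
Ypt53	aperiodic
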