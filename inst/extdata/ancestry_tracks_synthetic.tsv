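strain	chrom	start_mb	end_mb	subspecies
DBA	chr7	0	17.3	domesticus
DBA	chr7	17.3	32	musculus
DBA	chr7	32	33.5	castaneus
DBA	chr7	33.5	50.9	musculus
DBA	chr7	50.9	60	domesticus
C3H	chr7	0	60	domesticus
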