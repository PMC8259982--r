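# five validation 22q13 terminal deletions (hg19 breakpoints as printed)
# coordinates: 1-based start, half-open [start,end); length = end - start
patient_id	chrom	start	end	terminal	size_class
PMS1	chr22	42740931	51244566	TRUE	Large
PMS2	chr22	42816484	51244566	TRUE	Large
PMS3	chr22	43800990	51244566	TRUE	Mid
PMS4	chr22	47731071	51193680	TRUE	Small
PMS5	chr22	51123491	51224252	TRUE	Small
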