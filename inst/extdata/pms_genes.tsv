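# candidate-gene panel; 9 blood-expressed genes carry printed hg19 coordinates,
# FBLN1/SHANK3/SCO2 spans are approximate; hi_pct magnitudes are representative
# (synthetic) except that only ADSL and EP300 are <= 10%
# coordinates: 1-based start, half-open [start,end); length = end - start
symbol	chrom	start	end	hi_pct	phenotype_terms	expressed_in_blood
ADSL	chr22	40742504	40762575	9.3		TRUE
EP300	chr22	41488614	41576081	1.6		TRUE
TNFRSF13C	chr22	42321036	42322821	70		TRUE
NAGA	chr22	42454338	42466846	50		TRUE
A4GALT	chr22	43088127	43116876	55		TRUE
TRMU	chr22	46731298	46753237	60		TRUE
TUBGCP6	chr22	50656118	50683400	40		TRUE
SBF1	chr22	50883431	50913464	30		TRUE
ARSA	chr22	51061182	51066601	45		TRUE
FBLN1	chr22	45898712	45997440	15		FALSE
SHANK3	chr22	51113070	51171640	12		FALSE
SCO2	chr22	50961997	50964033	65		FALSE
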