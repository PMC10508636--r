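kind	param	value	note
ne	chimp	15000	synthetic stand-in
ne	nea1	2500	synthetic stand-in
ne	nea2	2500	synthetic stand-in
ne	den	2500	synthetic stand-in
ne	afr1	25000	synthetic stand-in
ne	afr2	25000	synthetic stand-in
ne	nonafr1	20000	synthetic stand-in
ne	nonafr2	20000	synthetic stand-in
ne	neaghost	2500	synthetic stand-in
ne	nea	2500	synthetic stand-in
ne	arch1	3000	synthetic stand-in
ne	arch	5000	synthetic stand-in
ne	amh	25000	synthetic stand-in
ne	afr	25000	synthetic stand-in
ne	ooa	2000	out-of-Africa bottleneck
ne	hom	20000	synthetic stand-in
ne	root	15000	synthetic stand-in
time	t_nonafr	1800	non-African 1/2 split
time	t_ooa	2800	out-of-Africa split
time	t_afr	3600	African 1/2 split
time	t_nea_split	5600	late Neanderthal / ghost split
time	t_nea1	9000	early Neanderthal split
time	t_arch_split	16000	Neanderthal / Denisovan split
time	t_hom	23000	modern / archaic split
time	t_root	240000	chimpanzee split
time	t_flow	2200	Neanderthal gene flow into non-African ancestor
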