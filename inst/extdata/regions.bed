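chr1	1000	1500	win01	0	+
chr1	1700	2200	win02	0	-
chr1	2400	2900	win03	0	+
chr1	3100	3600	win04	0	-
chr1	3800	4300	win05	0	+
chr1	4500	5000	win06	0	-
chr1	5200	5700	win07	0	+
chr1	5900	6400	win08	0	-
chr1	6600	7100	win09	0	+
chr1	7300	7800	win10	0	-
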