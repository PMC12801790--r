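# Synthetic hg19 1-Mb bin keep-mask (autosomes). Constructed stand-in for a
# real mappability/GC-track derived usable-bin list: bins are dropped around
# centromeres (+/- 7 Mb), across acrocentric p-arms, across the chr1/chr9/chr16
# heterochromatin gaps, and at each chromosome's first and terminal bin,
# yielding the conventional 2,475-bin autosomal feature space.
chrom	n_bins	dropped
chr1	250	0,118,119,120,121,122,123,124,125,126,127,128,129,130,131,249
chr2	244	0,86,87,88,89,90,91,92,93,94,95,96,97,98,99,100,243
chr3	199	0,84,85,86,87,88,89,90,91,92,93,94,95,96,97,198
chr4	192	0,43,44,45,46,47,48,49,50,51,52,53,54,55,56,57,191
chr5	181	0,41,42,43,44,45,46,47,48,49,50,51,52,53,54,55,180
chr6	172	0,54,55,56,57,58,59,60,61,62,63,64,65,66,67,171
chr7	160	0,52,53,54,55,56,57,58,59,60,61,62,63,64,65,66,159
chr8	147	0,38,39,40,41,42,43,44,45,46,47,48,49,50,51,52,146
chr9	142	0,42,43,44,45,46,47,48,49,50,51,52,53,54,55,56,57,58,59,60,61,62,63,64,65,66,141
chr10	136	0,33,34,35,36,37,38,39,40,41,42,43,44,45,46,47,135
chr11	136	0,46,47,48,49,50,51,52,53,54,55,56,57,58,59,60,135
chr12	134	0,28,29,30,31,32,33,34,35,36,37,38,39,40,41,42,133
chr13	116	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,115
chr14	108	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,107
chr15	103	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,25,102
chr16	91	0,29,30,31,32,33,34,35,36,37,38,39,40,41,42,43,44,45,46,90
chr17	82	0,17,18,19,20,21,22,23,24,25,26,27,28,29,30,81
chr18	79	0,10,11,12,13,14,15,16,17,18,19,20,21,22,23,24,78
chr19	60	0,19,20,21,22,23,24,25,26,27,28,29,30,31,32,33,59
chr20	64	0,20,21,22,23,24,25,26,27,28,29,30,31,32,33,34,63
chr21	49	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,48
chr22	52	0,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18,19,20,21,51
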