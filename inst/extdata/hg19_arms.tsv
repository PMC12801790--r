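1p	chr1	0	125000000	0
1q	chr1	125000000	249250621	0
2p	chr2	0	93300000	0
2q	chr2	93300000	243199373	0
3p	chr3	0	91000000	0
3q	chr3	91000000	198022430	0
4p	chr4	0	50400000	0
4q	chr4	50400000	191154276	0
5p	chr5	0	48400000	0
5q	chr5	48400000	180915260	0
6p	chr6	0	61000000	0
6q	chr6	61000000	171115067	0
7p	chr7	0	59900000	0
7q	chr7	59900000	159138663	0
8p	chr8	0	45600000	0
8q	chr8	45600000	146364022	0
9p	chr9	0	49000000	0
9q	chr9	49000000	141213431	0
10p	chr10	0	40200000	0
10q	chr10	40200000	135534747	0
11p	chr11	0	53700000	0
11q	chr11	53700000	135006516	0
12p	chr12	0	35800000	0
12q	chr12	35800000	133851895	0
13p	chr13	0	17900000	1
13q	chr13	17900000	115169878	0
14p	chr14	0	17600000	1
14q	chr14	17600000	107349540	0
15p	chr15	0	19000000	1
15q	chr15	19000000	102531392	0
16p	chr16	0	36600000	0
16q	chr16	36600000	90354753	0
17p	chr17	0	24000000	0
17q	chr17	24000000	81195210	0
18p	chr18	0	17200000	0
18q	chr18	17200000	78077248	0
19p	chr19	0	26500000	0
19q	chr19	26500000	59128983	0
20p	chr20	0	27500000	0
20q	chr20	27500000	63025520	0
21p	chr21	0	13200000	1
21q	chr21	13200000	48129895	0
22p	chr22	0	14700000	1
22q	chr22	14700000	51304566	0
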