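gene	nonsmoker_median	smoker_median	absolute_difference	fold_change
FTL	371.1	843.4	472.2	2.3
PRDX1	187	398.6	211.6	2.1
FTH1	349.2	551.5	202.3	1.6
NQO1	38.3	198.7	160.4	5.2
MSMB	333.1	3112.7	2779.6	9.3
C20orf114	1484.3	4102.7	2618.5	2.8
ALDH3A1	226.9	2077.9	1851	9.2
TFF3	149.4	697.9	548.5	4.7
WFDC2	840.3	1327	486.7	1.6
CRIP1	1014.1	587.7	-426.3	-1.7
RPLP1	916.1	516	-400.1	-1.8
SCGB1A1	38675.4	17244	-21431.5	-2.2
SCGB3A1	7838.2	2947.3	-4890.8	-2.7
CD74	947.2	723.7	-223.5	-1.3
CYP4B1	373.5	259.3	-114.2	-1.4
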