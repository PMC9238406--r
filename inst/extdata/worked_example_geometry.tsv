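panel	time	segment	observed	band	sign	fill
OTU_003	0	1	TRUE	1	1	5
OTU_003	0	1	TRUE	2	1	5
OTU_003	0	1	TRUE	3	1	5
OTU_003	0	1	TRUE	4	1	5
OTU_003	7	1	TRUE	1	1	5
OTU_003	7	1	TRUE	2	1	5
OTU_003	7	1	TRUE	3	1	0
OTU_003	7	1	TRUE	4	1	0
OTU_003	14	1	TRUE	1	0	0
OTU_003	14	1	TRUE	2	0	0
OTU_003	14	1	TRUE	3	0	0
OTU_003	14	1	TRUE	4	0	0
OTU_003	21	1	TRUE	1	-1	5
OTU_003	21	1	TRUE	2	-1	5
OTU_003	21	1	TRUE	3	-1	0
OTU_003	21	1	TRUE	4	-1	0
OTU_003	28	1	TRUE	1	-1	5
OTU_003	28	1	TRUE	2	-1	5
OTU_003	28	1	TRUE	3	-1	5
OTU_003	28	1	TRUE	4	-1	5
OTU_001	0	1	TRUE	1	-1	5
OTU_001	0	1	TRUE	2	-1	5
OTU_001	0	1	TRUE	3	-1	5
OTU_001	0	1	TRUE	4	-1	5
OTU_001	7	1	TRUE	1	-1	5
OTU_001	7	1	TRUE	2	-1	5
OTU_001	7	1	TRUE	3	-1	0
OTU_001	7	1	TRUE	4	-1	0
OTU_001	14	1	TRUE	1	0	0
OTU_001	14	1	TRUE	2	0	0
OTU_001	14	1	TRUE	3	0	0
OTU_001	14	1	TRUE	4	0	0
OTU_001	21	1	TRUE	1	1	5
OTU_001	21	1	TRUE	2	1	5
OTU_001	21	1	TRUE	3	1	0
OTU_001	21	1	TRUE	4	1	0
OTU_001	28	1	TRUE	1	1	5
OTU_001	28	1	TRUE	2	1	5
OTU_001	28	1	TRUE	3	1	5
OTU_001	28	1	TRUE	4	1	5
OTU_002	0	1	TRUE	1	0	0
OTU_002	0	1	TRUE	2	0	0
OTU_002	0	1	TRUE	3	0	0
OTU_002	0	1	TRUE	4	0	0
OTU_002	7	1	TRUE	1	0	0
OTU_002	7	1	TRUE	2	0	0
OTU_002	7	1	TRUE	3	0	0
OTU_002	7	1	TRUE	4	0	0
OTU_002	14	1	TRUE	1	0	0
OTU_002	14	1	TRUE	2	0	0
OTU_002	14	1	TRUE	3	0	0
OTU_002	14	1	TRUE	4	0	0
OTU_002	21	1	TRUE	1	0	0
OTU_002	21	1	TRUE	2	0	0
OTU_002	21	1	TRUE	3	0	0
OTU_002	21	1	TRUE	4	0	0
OTU_002	28	1	TRUE	1	0	0
OTU_002	28	1	TRUE	2	0	0
OTU_002	28	1	TRUE	3	0	0
OTU_002	28	1	TRUE	4	0	0
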