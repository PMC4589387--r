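rsid	chrom	pos	maf	gwas_p
rsSYN001	chr1	10000000	0.105	7.78e-08
rsSYN002	chr1	50000000	0.273	9.95e-07
rsSYN003	chr2	10000000	0.24	9.07e-09
rsSYN004	chr2	50000000	0.086	8.79e-07
rsSYN005	chr3	10000000	0.13	5.51e-07
rsSYN006	chr3	50000000	0.239	1.52e-10
rsSYN007	chr4	10000000	0.282	4.51e-07
rsSYN008	chr4	50000000	0.211	6.92e-08
rsSYN009	chr5	10000000	0.245	3e-10
rsSYN010	chr5	50000000	0.161	3.21e-07
rsSYN011	chr6	10000000	0.405	1.99e-07
rsSYN012	chr6	50000000	0.337	1.73e-08
rsSYN013	chr7	10000000	0.191	2.35e-10
rsSYN014	chr7	50000000	0.121	3.94e-10
rsSYN015	chr8	10000000	0.182	1.16e-09
rsSYN016	chr8	50000000	0.103	5.07e-09
rsSYN017	chr9	10000000	0.179	1.18e-08
rsSYN018	chr9	50000000	0.166	4.76e-08
rsSYN019	chr10	10000000	0.277	2.34e-07
rsSYN020	chr10	50000000	0.341	1.2e-08
rsSYN021	chr11	10000000	0.212	1.53e-07
rsSYN022	chr11	50000000	0.426	1.9e-09
rsSYN023	chr12	60000000	0.335	3.51e-08
rsSYN024	chr12	61000000	0.086	3.97e-08
rsSYN025	chr13	10000000	0.292	1e-09
rsSYN026	chr13	10500000	0.414	1e-07
rsSYN027	chr14	20000000	0.281	1e-10
rsSYN028	chr14	20600000	0.319	1e-06
rsSYN029	chr14	21100000	0.25	1e-07
rsSYN030	chr15	30000000	0.205	1e-08
rsSYN031	chr15	30300000	0.169	1e-06
rsSYN032	chr15	30600000	0.257	1e-07
rsSYN033	chr16	40000000	0.245	1e-09
rsSYN034	chr16	40999999	0.406	1e-05
rsSYN035	chr17	50000000	0.145	1e-08
rsSYN036	chr17	50200000	0.319	1e-06
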