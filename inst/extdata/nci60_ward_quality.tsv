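scenario	ward_cutoff	n_clusters	silhouette	calinski_harabasz	davies_bouldin
all	3.0	7	-0.014	4.84	77.19
all	2.5	9	-0.014	4.01	80.19
all	2.0	89	-0.022	1.77	28.63
all	1.5	2565	-0.106	1.28	7.28
all	1.0	17958	-0.257	1.05	2.59
all	0.5	33246	-0.305	1.01	1.43
non_outlier	3.0	4	-0.007	5.32	67.15
non_outlier	2.5	7	-0.009	3.50	69.94
non_outlier	2.0	88	-0.030	1.96	21.45
non_outlier	1.5	1766	-0.103	1.37	6.97
non_outlier	1.0	11436	-0.260	1.07	2.62
non_outlier	0.5	20723	-0.339	1.01	1.53
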