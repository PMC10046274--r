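quantity	value
n_molecules_all	50555
n_molecules_non_outlier	32971
outlier_cutoff	0.5
ward3_n_clusters_all	7
ward3_n_clusters_non_outlier	4
ward3_largest_cluster_all	17691
ward3_largest_cluster_non_outlier	15389
butina09_n_clusters_all	64
butina09_n_clusters_non_outlier	44
butina09_molecules_in_largest_cluster_all	45652
butina09_molecules_in_largest_cluster_non_outlier	30669
umap_k_low	7
umap_k_high	20
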