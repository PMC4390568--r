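qtl_id	chrom	qtl_start_mb	qtl_end_mb	significance	sweep_id	sweep_start_mb	sweep_end_mb	sweep_genes
AF3.I	3	18.61	32.15	suggestive	AF3.I-a	22.00	22.50	6
AF3.I	3	18.61	32.15	suggestive	AF3.I-b	24.03	24.16	2
AF3.I	3	18.61	32.15	suggestive	AF3.I-c	24.30	24.64	3
AF3.I	3	18.61	32.15	suggestive	AF3.I-d	26.05	26.10	0
AF3.I	3	18.61	32.15	suggestive	AF3.I-e	30.52	30.59	2
AF3.II	3	39.74	48.52	suggestive	AF3.II-a	40.28	40.30	0
AF3.II	3	39.74	48.52	suggestive	AF3.II-b	44.03	44.04	MLLT4
AF3.II	3	39.74	48.52	suggestive	AF3.II-c	46.57	46.60	PARK2
AF5	5	54.52	62.03	significant_1pct	AF5	54.65	54.65	JAG2
AF7	7	4.21	17.63	suggestive	AF7	5.31	5.52	2
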