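quantity	value
snps_total	11847150
snps_full_callrate	9422311
indels_total	1090316
indels_full_callrate	810754
snps_per_bird	2729525
genome_size_mb	1050.9
haploid_sample_size	10
recomb_rate_per_bp_per_gen	3e-8
total_generations	35
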