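class	n_fixed	baseline_percent
3_prime_UTR_variant	56	NA
5_prime_UTR_variant	23	NA
coding_sequence_variant	10	NA
downstream_gene_variant	1200	NA
intergenic_variant	12066	67.32
intron_variant	5775	25.35
missense_variant	180	0.35
non_coding_transcript_variant	9	NA
splice_acceptor_variant	3	NA
splice_donor_variant	3	NA
splice_region_variant	44	NA
stop_gained	3	NA
synonymous_variant	83	NA
upstream_gene_variant	1429	NA
Unknown	33	NA
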