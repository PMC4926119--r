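library	total_reads	low_quality	n_reads	too_short	too_long	clean_reads
AFCJ-S	23102322	0	1607	10578163	2891855	9630697
JCWL-R	24412341	0	2162	9905970	3669050	10835159
JCJT-R	21776191	0	194	9886698	1590788	10298511
JYJD-R	22652472	0	1423	7000606	3436202	12214241
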