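library	category	count	percent
AFCJ-S	total	9630697	100
AFCJ-S	miRNA	31101	0.32
AFCJ-S	rRNA	6196149	64.34
AFCJ-S	snRNA	5447	0.06
AFCJ-S	snoRNA	98	0.00
AFCJ-S	tRNA	302771	3.14
AFCJ-S	unannotated	3095131	32.14
JCWL-R	total	10835159	100
JCWL-R	miRNA	36595	0.34
JCWL-R	rRNA	7065510	65.21
JCWL-R	snRNA	5857	0.05
JCWL-R	snoRNA	68	0.00
JCWL-R	tRNA	334956	3.09
JCWL-R	unannotated	3392173	31.31
JCJT-R	total	10298511	100
JCJT-R	miRNA	103813	1.01
JCJT-R	rRNA	6026448	58.52
JCJT-R	snRNA	2542	0.02
JCJT-R	snoRNA	48	0.00
JCJT-R	tRNA	331495	3.22
JCJT-R	unannotated	3834165	37.23
JYJD-R	total	12214241	100
JYJD-R	miRNA	37788	0.31
JYJD-R	rRNA	7996614	65.47
JYJD-R	snRNA	4799	0.04
JYJD-R	snoRNA	69	0.00
JYJD-R	tRNA	455660	3.73
JYJD-R	unannotated	3719311	30.45
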