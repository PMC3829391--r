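plate_id	well_id	sample_kind	pool_id	firefly	renilla	replicate
P001	A01	pool	POOL00001	2100	980	1
P001	A02	pool	POOL00002	450	1020	1
P001	A03	pool	POOL00003	990	1005	1
P001	A04	empty	NA	5	1	1
P001	B01	negative_control	NA	1010	995	1
P001	B02	negative_control	NA	985	1001	1
P001	B03	negative_control	NA	1002	990	1
P001	B04	negative_control	NA	998	1012	1
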