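probe_id	Sample1	Sample2	Sample3	Sample4
Gene1	4	0.1	5	2
Gene2	3	1	2	2
Gene3	2	2	5	2
Gene4	1	3	1	2
Gene5	0.1	4	3	2
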