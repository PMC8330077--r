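species	Dnmt1	Dnmt2	Dnmt3	Tet	Tdg	Uhrf	Mbd1/2/3	Mbd4	Chd1/2	Chd3/4/5	Chd6/7/8/9	Hdac1/2	Hdac3	Hdac8	Rbbp4/7	Mta1/2/3	Gatad2
Sponge	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
Cnidarian	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
Platynereis_dumerilii	1	1	1	1	1	1	1	1	1	4	1	1	1	1	1	1	1
Drosophila	0	1	0	0	1	0	1	0	1	1	1	1	1	1	1	1	1
Human	1	1	2	3	1	2	4	1	2	3	4	2	1	1	2	3	2
Amphioxus	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
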