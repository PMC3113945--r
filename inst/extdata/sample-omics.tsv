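# sample expression datafile: rows are gene / reaction / compound labels,
# value columns are tab separated; one column per experiment
label	t0	t10	t30
demA	1.20	2.40	4.90
demB	0.80	1.10	1.60
RXN-HK	2.10	2.00	NA
CPD-GLC	5.00	2.50	1.20
argT	0.40	0.90	2.10
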