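MarkerName	Allele1	Allele2	Direction	p	N
rs1000001	A	G	+	4.2e-09	133000
rs1000002	C	T	-	3.1e-05	131500
rs1000003	G	A	+	0.47	132800
rs1000004	T	C	-	8.9e-12	130900
rs1000005	A	C	+	0.0021	133200
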