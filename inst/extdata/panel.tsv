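assay_id	legacy_name	ref_allele	alt_allele	region	panel_index
c.-1584C>G	-1584C>G	C	G	promoter	1
c.31G>A	31G>A	G	A	exon1	2
c.100C>T	100C>T	C	T	exon1	3
c.320C>T	1023C>T	C	T	mid	4
c.454delT	1707delT	T	del	mid	5
c.506-1G>A	1846G>A	G	A	mid	6
c.775delA	2549delA	A	del	mid	7
c.841_843delAAG	2615_2617delAAG	AAG	del	mid	8
c.844-12G>A	NA	G	A	mid	9
c.886C>T	2850C>T	C	T	mid	10
c.971G>A	2939G>A	G	A	mid	11
c.985+39G>A	2988G>A	G	A	mid	12
c.1012G>A	3183G>A	G	A	mid	13
c.1228G>A	3854G>A	G	A	mid	14
c.1457G>C	4180G>C	G	C	late	15
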