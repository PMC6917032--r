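record	field1	field2
chemical_mapping	MESH:C106538	PA448004
chemical_mapping	MESH:D014859	PA451906
chemical_mapping	MESH:C055162	PA449053
chemical_mapping	MESH:D016559	PA451578
association	PA448004	HLA-B*57:01
association	PA451906	rs1057910
association	PA449053;PA451906	rs662
association	PA451578	CYP3A5*3
association	PA451906	VKORC1*2
star_rs	POR*28	rs1057868
star_rs	VKORC1*2	rs9923231
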