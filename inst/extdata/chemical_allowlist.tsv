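mesh_id	name	categories
MESH:D014859	warfarin	drug
MESH:C055162	clopidogrel	drug
MESH:D019821	simvastatin	drug
MESH:C106538	abacavir	drug
MESH:C084178	telmisartan	drug
MESH:D002220	carbamazepine	drug
MESH:D001379	azathioprine	drug
MESH:D003024	clozapine	drug
MESH:C098320	efavirenz	drug
MESH:D009853	omeprazole	drug
MESH:D008790	metoprolol	drug
MESH:D016559	tacrolimus	drug
MESH:D003061	codeine	drug
MESH:D014635	valproic acid	drug
MESH:D009173	mycophenolic acid	drug
MESH:D016898	interferon alpha	drug
MESH:D016899	interferon beta	drug
MESH:D000069347	erlotinib	drug
MESH:D000077156	gefitinib	drug
MESH:D013629	tamoxifen	drug
MESH:D000077146	irinotecan	drug
MESH:D005472	fluorouracil	drug
MESH:D000255	ATP	drug
MESH:D013395	sucrose	excipient
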