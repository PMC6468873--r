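gene	family	genetic_variant	path_tools	pop_freq	function_text
BRCA2	FAM20	c.4963delT p.(Tyr1655fs*15)	FS	0/60,706	Double-strand break repair via homologous recombination, inherited predisposition to breast and ovarian cancer
BLM	FAMN4	c.2069C>T p.(Pro690Leu)	6/6	1/60,570	DNA helicase, double-strand break repair via homologous recombination, regulation of cell cycle and apoptosis, DNA replication, telomere maintenance
ERCC2	H458	c.688G>A p.(Val230Ile)	4/6	0/60,706	DNA helicase, transcription-coupled nucleotide excision repair, regulation of cell cycle
FAT2	FAMN3	c.1643T>C p.(Val548Ala)	5/6	0/60,706	Regulation of cell proliferation, cell adhesion
IGF2R	H466	c.232G>A p.(Gly78Arg)	6/6	1/60,684	Positive regulation of apoptosis
LATS2	H460	c.337G>A p.(Asp113Asn)	5/6	1/56,138	Positive regulation of apoptosis, regulation of cell cycle
PARP2	FAM20	c.910G>C p.(Glu304Gln)	3/6	3/60,208	Base excision repair, extrinsic apoptotic signaling pathway
PSMD9	H469	c.361A>T p.(Ser121Cys)	3/6	30/60,148	Subunit of 26S proteasome, regulation of apoptosis and cell cycle, regulation of ubiquitin-protein ligase activity
RASSF6	H460	c.779C>T p.(Pro260Leu)	6/6	53/60,475	Positive regulation of apoptosis
RECQL	H466	c.221_225delinsAATGT p.(Pro74_Trp75delinsGlnCys)	6/6	0/60,706	DNA helicase, double-strand break repair via homologous recombination, DNA replication
RERGL	H466	c.362T>C p.(Val121Ala)	6/6	54/60,446	Unknown (closely related to RERG, a negative regulator of cell growth)
REV3L	FAM3	c.559A>T p.(Arg187Trp)	5/6	0/60,706	DNA repair, translesion DNA synthesis
RIF1	H460	c.4262G>A p.(Arg1421His)	4/6	5/59,938	Double-strand break repair via nonhomologous end joining, telomere maintenance
SEC23B	H470	c.531G>C p.(Glu177Asp)	4/6	1/60,706	Intracellular protein transport, associated with inherited cancer predisposition Cowden Syndrome
SMARCA4	FAM3	c.295C>T p.(Arg99Trp)	5/6	1/60,196	Regulation of cell growth, regulation of cell cycle, chromatin remodeling
STK11IP	H470	c.1214C>T p.(Pro405Leu)	5/6	51/59,930	Interaction with STK11 (serine/threonine kinase activity, negative regulation of cell growth, Peutz-Jeghers CRC predisposition syndrome)
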