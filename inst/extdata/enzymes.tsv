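# Restriction-enzyme catalog: commercially available type IIP enzymes that
# cut within their recognition site. Recognition sites in uppercase IUPAC
# code; '^' marks the top-strand cut position.
# Source: compiled from the public REBASE enzyme listing (rebase.neb.com),
# prototype/commercial sites as of 2016. This is a reconstruction: the
# catalog is user-replaceable and results of combinatorial searches depend
# on its content.
# Format: name<TAB>site
AatII	GACGT^C
AccI	GT^MKAC
AclI	AA^CGTT
AfeI	AGC^GCT
AflII	C^TTAAG
AgeI	A^CCGGT
AluI	AG^CT
ApaI	GGGCC^C
ApaLI	G^TGCAC
AseI	AT^TAAT
AvaI	C^YCGRG
AvaII	G^GWCC
AvrII	C^CTAGG
BamHI	G^GATCC
BanI	G^GYRCC
BanII	GRGCY^C
BclI	T^GATCA
BfaI	C^TAG
BfuCI	^GATC
BglII	A^GATCT
BsiWI	C^GTACG
BspEI	T^CCGGA
BspHI	T^CATGA
BsrGI	T^GTACA
BssHII	G^CGCGC
BstBI	TT^CGAA
BstZ17I	GTA^TAC
ClaI	AT^CGAT
Csp6I	G^TAC
CviJI	RG^CY
DdeI	C^TNAG
DraI	TTT^AAA
EagI	C^GGCCG
EcoRI	G^AATTC
EcoRV	GAT^ATC
FseI	GGCCGG^CC
FspI	TGC^GCA
HaeII	RGCGC^Y
HaeIII	GG^CC
HhaI	GCG^C
HincII	GTY^RAC
HindIII	A^AGCTT
HinfI	G^ANTC
HpaI	GTT^AAC
KasI	G^GCGCC
KpnI	GGTAC^C
MfeI	C^AATTG
MluI	A^CGCGT
MseI	T^TAA
MspI	C^CGG
NaeI	GCC^GGC
NcoI	C^CATGG
NdeI	CA^TATG
NheI	G^CTAGC
NlaIII	CATG^
NotI	GC^GGCCGC
NruI	TCG^CGA
NsiI	ATGCA^T
NspI	RCATG^Y
PacI	TTAAT^TAA
PciI	A^CATGT
PmlI	CAC^GTG
PstI	CTGCA^G
PvuI	CGAT^CG
PvuII	CAG^CTG
RsaI	GT^AC
SacI	GAGCT^C
SacII	CCGC^GG
SalI	G^TCGAC
Sau96I	G^GNCC
ScaI	AGT^ACT
ScrFI	CC^NGG
SmaI	CCC^GGG
SnaBI	TAC^GTA
SpeI	A^CTAGT
SphI	GCATG^C
Sse9I	^AATT
SspI	AAT^ATT
StuI	AGG^CCT
StyI	C^CWWGG
SwaI	ATTT^AAAT
TaqI	T^CGA
TfiI	G^AWTC
XbaI	T^CTAGA
XhoI	C^TCGAG
XmaI	C^CCGGG
ZraI	GAC^GTC
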