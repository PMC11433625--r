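# Starter panel of common restriction endonucleases for ITS PCR-RFLP work.
# Format: name<TAB>site, with ^ marking the top-strand cut position.
# Grouped names (A/B/C) are site-isoschizomers reported as one entry.
# Sites transcribed from REBASE; verify offsets against current REBASE
# before relying on them for anything beyond fragment-length work.
AluI	AG^CT
AvaI	C^YCGRG
AvaII	G^GWCC
BamHI	G^GATCC
BfaI	C^TAG
BstNI	CC^WGG
Cac8I	GCN^NGC
CfoI/HhaI/HinP1I	GCG^C
CviAII/NlaIII	CATG^
DdeI	C^TNAG
DraI	TTT^AAA
EcoRI	G^AATTC
EcoRV	GAT^ATC
FaiI	YA^TR
Fnu4HI	GC^NGC
HaeIII	GG^CC
HindIII	A^AGCTT
HinfI	G^ANTC
HpaII	C^CGG
Hpy8I	GTN^NAC
HpyCH4VI/MaeII/TaiI	A^CGT
MboI	^GATC
MfeI	C^AATTG
MseI	T^TAA
NcoI	C^CATGG
NlaIV	GGN^NCC
RsaI	GT^AC
Sau96I	G^GNCC
ScrFI	CC^NGG
SpeI	A^CTAGT
StuI	AGG^CCT
StyI	C^CWWGG
TaqI	T^CGA
TauI	GCSG^C
Tsp509I	^AATT
XbaI	T^CTAGA
XmaIII	C^GGCCG
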