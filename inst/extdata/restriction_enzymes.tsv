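enzyme	site
BamHI	GGATCC
BglII	AGATCT
EcoRI	GAATTC
EcoRV	GATATC
HindIII	AAGCTT
KpnI	GGTACC
NcoI	CCATGG
NdeI	CATATG
NheI	GCTAGC
NotI	GCGGCCGC
PstI	CTGCAG
SacI	GAGCTC
SalI	GTCGAC
SmaI	CCCGGG
SpeI	ACTAGT
XbaI	TCTAGA
XhoI	CTCGAG
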