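prefix	pattern	implied_type	entity_types	rank	example
uniprotkb	^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})(-[0-9]+)?$	mi:0326	protein	primary	P07948
ensembl	^ENS[A-Z]{0,5}[GTP][0-9]{11}([.][0-9]+)?$		gene|mrna|rna	primary	ENST00000519728
ncbigene	^[0-9]+$		gene|protein	alternative	4067
refseq	^[A-Z]{2}_[0-9]+([.][0-9]+)?$		gene|mrna|rna|protein	alternative	NM_002350
hgnc	^[0-9]+$		gene	alternative	6735
mirbase	^MI(MAT)?[0-9]{7}$		rna	alternative	MIMAT0000062
chebi	^[0-9]+$	mi:0328	chemical	primary	29101
pubchem.compound	^[0-9]+$	mi:0328	chemical	alternative	5790
complexportal	^CPX-[0-9]+$	mi:0314	complex	primary	CPX-1861
signor	^SIGNOR-[A-Z0-9]+$		family|complex|phenotype	alternative	SIGNOR-PF24
go	^[0-9]{7}$		phenotype	primary	0006915
mi	^[0-9]{4}$			primary	0217
ro	^[0-9]{7}$			primary	0002629
eco	^[0-9]{7}$			primary	0000006
mod	^[0-9]{5}$			primary	00048
so	^[0-9]{7}$			primary	0000409
ncbitaxon	^[0-9]+$			primary	9606
pubmed	^[0-9]+$			primary	10592173
doi	^10[.][0-9]{2,9}/[^[:space:]]+$			primary	10.1000/demo123
bto	^[0-9]{7}$			primary	0000089
uberon	^[0-9]{7}$			primary	0002107
cl	^[0-9]{7}$			primary	0000236
cellosaurus	^CVCL_[A-Z0-9]{4}$			primary	CVCL_0030
obi	^[0-9]{7}$			primary	0000070
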