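# Pan-assay interference (PAINS) substructure patterns.
# Curated subset of the published PAINS catalogues (families A/B/C,
# Baell & Holloway, J. Med. Chem. 2010, 53, 2719), written as SMARTS.
# Columns: name <tab> smarts
catechol_A	Oc1ccccc1O
hydroquinone_A	Oc1ccc(O)cc1
quinone_A	O=C1C=CC(=O)C=C1
quinone_B	O=C1C=CC=CC1=O
rhodanine_A	O=C1CSC(=S)N1
ene_rhodanine_A	O=C1NC(=S)SC1=C
azo_A	cN=Nc
hzone_phenol_A	Oc1ccccc1C=NN
thiourea_A	NC(=S)N
isothiocyanate_A	N=C=S
maleimide_A	O=C1C=CC(=O)N1
ene_one_A	O=C(C=Cc1ccccc1)c1ccccc1
anhydride_A	C(=O)OC(=O)
alkylidene_barbiturate_A	O=C1NC(=O)NC(=O)C1=C
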