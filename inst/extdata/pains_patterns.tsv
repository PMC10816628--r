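# Assay-interference (PAINS-family) substructure motifs, restricted-SMILES form.
# id	smiles
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C=CC=CC1=O
catechol	Oc1ccccc1O
azo_aryl	cN=Nc
rhodanine	S=C1NC(=O)CS1
phenol_hydrazone	cC=NNc
thiourea	NC(=S)N
isothiazolone	O=C1C=CSN1
hydroxyphenyl_amine	Nc1ccccc1O
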