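gene	gene_name
CCDC59	Coiled-coil domain containing 59
SLC29A3	Solute carrier family 29 (nucleoside transporters), member 3
MCFD2	Multiple coagulation factor deficiency 2
RPL28	Ribosomal protein 28
PSMD1	Proteasome 26S subunit, non-ATPase 1
MYCBP	c-MYC binding protein
IKBKB	Inhibitor of nuclear factor kappa B kinase subunit Beta
RRM1	Ribonucleotide reductase subunit M1
GNB1	Guanine nucleotide binding protein subunit Beta 1
SSX2IP	Synovial sarcoma X breakpoint 2 interacting protein
PHC1	Polyhomeotic homolog 1
M6PR	Mannose 6-phophate receptor
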