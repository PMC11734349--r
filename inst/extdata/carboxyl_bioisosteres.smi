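# Curated default list of 13 non-classical bioisosteres of the carboxyl
# group, assembled from standard medicinal-chemistry practice. This is an
# editable configuration file, not an authoritative reference set.
smiles	name
*c1nnn[nH]1	tetrazole
*C(=O)NS(C)(=O)=O	acylsulfonamide
*S(N)(=O)=O	sulfonamide
*S(O)(=O)=O	sulfonic_acid
*S(O)=O	sulfinic_acid
*P(O)(O)=O	phosphonic_acid
*C(=O)NO	hydroxamic_acid
*B(O)O	boronic_acid
*C1=NOC(=O)N1	oxadiazolone
*C1=NN=C(O)O1	hydroxyoxadiazole
*C1=CC(O)=NO1	hydroxyisoxazole
*C1SC(=O)NC1=O	thiazolidinedione
*NS(=O)(=O)C(F)(F)F	triflamide
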