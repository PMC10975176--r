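name	target	residue	formula	diagnostic_losses	prefix	enabled	notes
benzoyl	N-term		C7H4O		Bz	TRUE	N-terminal benzoylation; acyl b1/a1 diagnostic ions
carboxybenzoyl	N-term		C8H4O3	CO2;CH2O3	cBz	TRUE	carboxyl on the benzoyl ring, position undetermined; precursor loses CO2 then H2O
pyroglutamate	N-term	E	H-2O-1		pE	TRUE	cyclized N-terminal Glu (loss of water)
pyroglutamate-Q	N-term	Q	H-3N-1		pQ	FALSE	Gln-derived pyro-Glu variant (loss of ammonia); disabled by default
amidation	C-term		HNO-1		NH2	TRUE	C-terminal amide replaces the free-acid hydroxyl (-0.98402 Da)
oxidation	residue	M	O		ox	TRUE	methionine sulfoxide (+15.99491 Da)
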