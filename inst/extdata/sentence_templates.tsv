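id	kind	pattern
hydroxyl	fine	^The molecule contains a hydroxyl group\.$
acid	fine	^The molecule contains a carboxylic acid group\.$
amine	fine	^The molecule contains a primary amine group\.$
halogen	fine	^The molecule carries a (fluorine|chlorine|bromine) substituent\.$
aromatic_ring	fine	^The molecule includes an aromatic ring of 6 atoms\.$
ring_size	fine	^The molecule includes a ring of ([0-9]+) atoms\.$
acyclic	fine	^The molecule contains no rings\.$
branched	fine	^The molecule has a branched carbon skeleton\.$
heavy_atoms	fine	^The molecule has ([0-9]+) heavy atoms\.$
aromatic_general	general	^The molecule is an aromatic compound\.$
role_acid	general	^The molecule has a role as an acidic reagent\.$
role_alcohol	general	^The molecule has a role as an alcohol solvent\.$
role_amine	general	^The molecule has a role as a basic reagent\.$
role_halogenated	general	^The molecule has a role as a halogenated reagent\.$
role_hydrocarbon	general	^The molecule has a role as a hydrocarbon feedstock\.$
organic_general	general	^The molecule is an organic compound\.$
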