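BreedA_01	BreedA	European
BreedA_02	BreedA	European
BreedA_03	BreedA	European
BreedB_01	BreedB	Asian
BreedB_02	BreedB	Asian
Warthog	Warthog	Outgroup
REF	Reference	Unassigned
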