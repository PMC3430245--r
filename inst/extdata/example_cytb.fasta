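>BreedA_01
TCAGACGTTCGTGTCAATCTAATTGGACCGTGAGATTCTGCTCGGGTTTGGGGGCCGATA
>BreedA_02
TCAGACGTTCGTGTCAATCTAATTGGACCGTGAGATTCTGCTCGGGTTTGGGGGCCGATA
>BreedA_03
TCAGACGTTCGTGTCAATCTAATTGGACCGTGAGATTCTGCTCGGGTTTGGGGGCCGATA
>BreedB_01
TCAGACGTTCGTGTCAATCTAATTGGACCGTGGGGTTCTGCTCGGGTTTGGGGGCCGATA
>BreedB_02
TCAGACGTTCGTGTCAATCTAATTGGACCGTGGGGTTCTGCTCGGGTTTGGGGGCCGATA
>Warthog
TCAGATGTTCGTGTTGATCGAACTGAACTGGGGGGTCCTGCCCGGGTCTGGGGGCCGATA
>REF
TCAGACGTTCGTGTCAATCTAATTGGACCGTGGGGTTCTGCTCGGGTTTGGGGGCCGATA
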