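>BreedA_01
TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
>BreedA_02
TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
>BreedA_03
TATCCAGCCATCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCACGGTTAG
>BreedB_01
TATCCAGC-CTCTATTGTACTCCTACCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
>BreedB_02
TATCCAGC-CTCTATTGTACTCCTACCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
>Warthog
CATCCAGCTATCTATTGTACTCCTATCTCAGCGTCTATGTCGCTTCGATTGCGCGATTAG
>REF
TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
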