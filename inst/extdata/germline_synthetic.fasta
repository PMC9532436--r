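>TRDV1|V|cys=24
GACAAAGTAACTCAGAGTCAGCCGTGTGCTCTTGGGGAA
>TRDV2|V|cys=24
GCCATTTACTCAAGTGGTGCAGATTGTGCCTGTGACACC
>TRDV3|V|cys=24
GTTGGAATGACGATTCAGCCTAAATGTGCCTTTAGGACC
>TRAV38-2DV8|V|cys=24
GCCCAGACAGTCACTCAGTCTCAATGTGCTTATAGGAGC
>TRGV8|V|cys=24
CTTCAGGAACTCCAGAAGGGTCAATGTGCCACCTGGGAC
>TRGV9|V|cys=24
GGGGAACTCACCTCTAACGGTCGTTGTGCCTTGTGGGAG
>TRGV2|V|cys=24
GATTCCGTGACTCAATTGGACGGTTGTGCCACGTGGGCT
>TRDD1|D
TACTGGGGAAGTAGT
>TRDD2|D
TCCTGGGGGATACC
>TRDD3|D
ACTGGGGGATACAGC
>TRDJ1|J|anchor=15
ACCGATAAACTCATCTTTGGAAAAGGAACC
>TRDJ2|J|anchor=27
CTCTGGGACACCACCCGACAGATGTTTTTCGGAAAAGGAACC
>TRDJ3|J|anchor=24
ACTTGGGACACCCGACAGATGTTTTTCGGAAAAGGAACC
>TRGJP|J|anchor=30
GTTCAAGAGTTGGGCAAAAAAATCAAGGTATTTGGAAAAGGAACC
>TRGJP1|J|anchor=21
ACCACTGGTTGGTTCAAGATATTTGGAAAAGGAACC
>TRGJ1|J|anchor=18
AATTATTATAAGAAACTCTTTGGAAAAGGAACC
>TRGJ2|J|anchor=18
AGTTATTATAAGAAACTCTTTGGAAAAGGAACC
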