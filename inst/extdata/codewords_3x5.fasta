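>s
CTATC
>e
AACTC
>A1
TAAAA
>A2
CTTTT
>A3
TTCAA
>B1
AATTA
>B2
CATTA
>B3
ATCTA
>B4
CAAAC
>B5
ATCCA
>w_1_1
CCCAT
>w_1_2
ATATA
>w_1_3
TTACA
>w_1_4
TACCC
>w_1_5
TTCTT
>w_2_1
TTTCA
>w_2_2
ATAAT
>w_2_3
CTACC
>w_2_4
TTACA
>w_2_5
CATAC
>w_3_1
CCTTC
>w_3_2
ACTCA
>w_3_3
TCACT
>w_3_4
ACCCT
>w_3_5
TTAAC
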