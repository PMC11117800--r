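>synthetic_glycine_rich synthetic test protein (not a real sequence)
LNSLGVLGGLHTTGGVTGGHGAQGNNGGGGEGGAGTGGCGRGVGNQGGGGGGGSGRLGGQ
GPPWGTYLRTDNGGSDGCDGILNGWNRETCYGYHGEGCGEGNMAGDGGGKTDRGCFPGGI
GGDQGGVNYMTIGGGCGCFVVKCVVQCGVG
>synthetic_tryptophan_rich synthetic test protein (not a real sequence)
WSTAWWSSWHDPWWWWWWRYWWSWWWHWWWGWWWWLTVECQLWVWMRWGWNWWTTWWWWI
WYWQEVDAKDEENWWYWWGKWYHWVNCIWPAWWWPPMWKIKRWRVWNWYNIHLEFRVMSQ
>synthetic_leucine_rich synthetic test protein (not a real sequence)
FMLLHWRLLTLLCLWYETYLMGQLKLLLLMQVEWTQLMLYLLKGLVLRLAAFLHCCRPWL
NWCGVPMLHPLIVLQLLNLCLLMLLDLHYLLLLDLLTLGLIYASFSQLSLTCLQCLWLLD
ARTYLELWLSMFKDGLLLAC
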