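>sp|P05413|FABP3_HUMAN Fatty acid-binding protein, heart
M--VDAFLGTWKLVDSKNFDDYMKSLGVGFATRQVASMTKPTTIIEKNGDILTLKTHSTF
KNTEISFKLGVEFDETTADDRKVKSIVTLDGGKLVHLQKWDGQETTLVRELIDGKLILTL
THGTAVCTRTYEKEA
>sp|P15090|FABP4_HUMAN Fatty acid-binding protein, adipocyte
M--CDAFVGTWKLVSSENFDDYMKEVGVGFATRKVAGMAKPNMIISVNGDLVTIKSESTF
KNTEISFILGQEFDETTADDRKVKSIITLDGGALVQVQKWDGKSTTIKRKRDGDKLVVEC
VMKGVTSTRVYER-A
>sp|Q01469|FABP5_HUMAN Fatty acid-binding protein, epidermal
MATVQQLEGRWRLVDSKGFDEYMKELGVGIALRKMGAMAKPDCIITCDGKNLTIKTESTL
KTTQFSCTLGEKFEETTADGRKTQTVCNFTDGALVQHQEWDGKESTITRKLKDGKLVVEC
VMNNVTCTRIYEKVE
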