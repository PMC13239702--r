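>sp|Q01469|FABP5_HUMAN Fatty acid-binding protein, epidermal
MATVQQLEGRWRLVDSKGFDEYMKELGVGIALRKMGAMAKPDCIITCDGKNLTIKTESTL
KTTQFSCTLGEKFEETTADGRKTQTVCNFTDGALVQHQEWDGKESTITRKLKDGKLVVEC
VMNNVTCTRIYEKVE
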