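>sp|P15090|FABP4_HUMAN Fatty acid-binding protein, adipocyte
MCDAFVGTWKLVSSENFDDYMKEVGVGFATRKVAGMAKPNMIISVNGDLVTIKSESTFKN
TEISFILGQEFDETTADDRKVKSIITLDGGALVQVQKWDGKSTTIKRKRDGDKLVVECVM
KGVTSTRVYERA
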