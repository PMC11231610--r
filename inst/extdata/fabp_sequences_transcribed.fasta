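>FABP3 heart-type fatty acid binding protein (literature transcription, not a database export)
MVDAFLGTWKLVDSKNFDDYMKSLGVGFATRQVASMTKPTTIIEKNGDILTLKTHSTFKN
TEISFKLGVEFDETTADDRKVKSIVTLDGGKLVHLQKWDGQETTLVRELIDGKLILTLTH
GTAVCTRTYEKEA
>FABP4 adipocyte-type fatty acid binding protein (literature transcription, not a database export)
MCDAFVGTWKLVSSENFDDYMKEVGVGFATRKVAGMAKPNMIISVNGDLVTIRSESTFKN
TEISFILGQEFDEVTADDRKVKSIITLDGGVLVHVQKWDGKSTTIKRKREDDKLVVECVM
KGVTSTRVYERA
>FABP5 epidermal-type fatty acid binding protein (literature transcription, not a database export)
MATVQQLEGRWRLVDSKGFDEYMKELGVGIALRKMGAMAKPDCIITCDGKNLTIKTESTL
KTTQFSCTLGEKFEETTADGRKTQTVCNFTDGALVQHQEWDGKESTITRKLKDGKLVVEC
VMNNVTCTRIYEKVE
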