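# Built-in motif patterns (X = any residue; [..] = alternatives).
# context: any | nterm:<n> (hit starts within first n residues)
#         | cterm:<n> (hit ends within last n residues)
name	pattern	context
FES4	CXXCXXCXXXC	any
FE2S2	CXXC	any
ROSSMANN_NAD	GXGXXG	any
ROSSMANN_NADP	GXGXXA	any
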