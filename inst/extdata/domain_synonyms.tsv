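# External domain identifiers mapped onto the hdrascan controlled vocabulary.
# Edit freely: the CD-Search output dialect differs between runs/versions.
alias	label
cl34141	TRX_FAD
cl48997	TRX_FAD
GOG1148	TRX_FAD
TRX_FAD_evidence	TRX_FAD
Pyr_redox	TRX_FAD
Pyr_redox_2	TRX_FAD
Fer4	FeS_extra
Fer2	MvhD
GltD_small	GltD
MvhD_2Fe2S	MvhD
HdrA_Nterm_FeS	FeS_N
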