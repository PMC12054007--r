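# The 28-class HdrA catalog: class name, major type, ordered domain template.
# Template tokens are comma-separated domain labels (see hdra_domain_labels()).
# The 12 text-anchored classes (A0, A1, A1-C, A6, A12, A2-1, A3, A4, A3+MVH,
# A9, A9-TRX-C, A10) follow their published descriptions; the remaining 16
# templates are a synthetic transcription constrained by the published class
# counts per type (13/5/7/3), the 2-8 domain range, and the type definitions.
class_name	major_type	template
A0	I	TRX_FAD,TRX_FeS
A1	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,Fd_C
A1-C	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins
A1-N	I	TRX_FAD,TRX_FeS,Fd_ins,Fd_C
A5	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,Fd_C,FeS_extra
A6	I	TRX_FAD,TRX_FeS,Fd_ins
A7	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,FeS_extra
A8	I	TRX_FAD,TRX_FeS,Fd_ins,FeS_extra
A11	I	FeS_N,FeS_extra,TRX_FAD,TRX_FeS,Fd_ins,Fd_C
A12	I	FeS_N,TRX_FAD,TRX_FeS
A13	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,FeS_extra,Fd_C
A14	I	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,Fd_C,FeS_extra,FeS_extra
A15	I	TRX_FAD,TRX_FeS,Fd_ins,Fd_C,FeS_extra
A2-1	Ia	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,Fd_C,MvhD
A2-2	Ia	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,MvhD
A2-3	Ia	TRX_FAD,TRX_FeS,Fd_ins,MvhD
A2-4	Ia	TRX_FAD,TRX_FeS,Fd_ins,Fd_C,MvhD
A2-5	Ia	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,Fd_C,FeS_extra,MvhD
A3	II	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS,Fd_ins
A3-2	II	FeS_N,TRX_FAD,TRX_FeS,TRX_FAD,TRX_FeS,Fd_ins
A3-C	II	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS
A3+MVH	II	FeS_N,TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS,Fd_ins,MvhD
A4	II	TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS,Fd_ins
A4-C	II	TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS
A4+FS	II	FeS_N,FeS_extra,TRX_FAD,TRX_FeS,Fd_ins,TRX_FAD,TRX_FeS,Fd_ins
A9	III	TRX_FAD,TRX_FeS,GltD,Fd_ins
A9-TRX-C	III	TRX_FAD,TRX_FeS,GltD,Fd_ins,FeS_extra
A10	III	FeS_N,TRX_FAD,TRX_FeS,GltD,Fd_ins,Fd_C
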