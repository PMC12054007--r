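# FBEB/FBEC inference rulebook. For each prediction field, rows are tried in
# priority order (most specific first) and the first row whose condition holds
# fires. Condition atoms: label:<gene>  type:<hdrA type>  molybdop_blocked
# lone  always; atoms are joined with & (all required), alternatives with |.
# confidence=validated marks experimentally validated reactions.
field	priority	requires	value	confidence	note
mid	1	type:III	NADH	predicted	NADH donor inferred for the GltD-carrying type III complex
mid	2	label:fdhB&molybdop_blocked	F420H2	predicted	F420H2 via FdhB with a non-catalytic Molybdop scaffold
mid	3	label:fdhA&label:fdhB	formate	validated	formate oxidation via FdhAB
mid	4	label:mvhA&label:mvhG	H2	validated	H2 oxidation via the MvhAG [NiFe]-hydrogenase
mid	5	lone	unknown	predicted	lone hdrA, no donor genes in cluster
mid	6	always	unknown	predicted	no recognized mid-potential donor genes
high	1	label:hdrB&label:hdrC	CoM-S-S-CoB via HdrBC	validated	heterodisulfide reduction at the HdrB [4Fe-4S] site
high	2	label:hdrD	CoM-S-S-CoB via HdrD	predicted	heterodisulfide reduction via HdrD
high	3	always	none-detected	predicted	no heterodisulfide-reducing subunit genes
low	1	label:fwd|label:fmd	CO2->formyl-MFR	validated	CO2 reduction to formyl-methanofuran via Fwd/Fmd
low	2	type:III	H2-evolution	predicted	H+ reduction to H2 proposed for type III complexes
low	3	lone	none	predicted	lone hdrA
low	4	always	Fd	validated	low-potential ferredoxin reduction by HdrA itself
note	1	type:II&second_hdrA_typeI	two-step bifurcation hypothesis	predicted	type I hdrA co-occurring with type II may chain two bifurcations
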