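# Core-region segment mask for extract_segment_mask(): 0-based half-open
# segments in reference residue coordinates. Empty by default — the manually
# curated FAD-contact segments are a property of a specific reference
# structure and must be supplied by the analyst for their chosen reference.
start	end
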