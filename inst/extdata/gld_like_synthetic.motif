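# Synthetic GLD-like motif model (constructed stand-in; the published motif
# exists only as a sequence-LOGO image, so no transcription is shipped).
# Matches the simulator's default planted family motif.
# format: name <whitespace> pattern; tokens: letter, . (any), [SET]
GLD_like_synthetic	G[ST]LD[FY]VWELKAG
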