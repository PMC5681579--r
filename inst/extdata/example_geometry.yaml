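# Example funiculus geometry for a medium-sized tephritid.
# SYNTHETIC plausibility values for demonstration and testing only --
# not measured dimensions. Measure your own species and replace.
species: synthetic_tephritid
length_mm: 0.6
width_mm: 0.3
thickness_mm: 0.25
positions_norm: [0.0, 0.333333333333, 0.666666666667, 1.0]
sigma: 10
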