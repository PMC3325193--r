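species	pseudofragment_bp	genome_bp	n_fragments
Huperzia_squarrosa	18026	413530	69
Marchantia_polymorpha	5402	186609	NA
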