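subgenus	n_dataset
Rhododendron	137
Pseudazalea	3
Pseudorhodorastrum	8
Rhodorastrum	2
Hymenanthes	181
Azaleastrum	18
Pentanthera	2
Tsutsusi	61
Therorhodion	1
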