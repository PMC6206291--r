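subgenus	n_described
Rhododendron	184
Pseudazalea	6
Pseudorhodorastrum	10
Rhodorastrum	2
Hymenanthes	259
Azaleastrum	26
Pentanthera	2
Tsutsusi	81
Therorhodion	1
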