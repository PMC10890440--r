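pathway_id	node_a	node_b
sp_amino	known_001	known_002
sp_amino	known_001	known_003
sp_amino	known_001	known_004
sp_amino	known_001	known_005
sp_amino	known_001	known_006
sp_amino	known_001	known_007
sp_amino	known_001	known_008
sp_amino	known_001	known_009
sp_amino	known_001	known_010
sp_amino	known_001	known_011
sp_amino	known_001	known_012
sp_amino	known_012	known_050
sp_amino	known_050	known_051
sp_amino	known_051	known_052
sp_amino	known_052	known_053
sp_amino	known_053	known_054
sp_amino	known_054	known_055
sp_sugar	known_060	known_061
sp_sugar	known_061	known_062
sp_sugar	known_062	known_063
sp_sugar	known_063	known_064
sp_sugar	known_064	known_065
sp_sugar	known_065	known_066
sp_sugar	known_066	known_067
sp_sugar	known_067	known_068
sp_sugar	known_068	known_069
sp_sugar	known_069	known_070
sp_sugar	known_070	known_071
sp_sugar	known_071	known_072
sp_sugar	known_072	known_073
sp_sugar	known_073	known_074
sp_sugar	known_074	known_075
sp_lipid	known_021	known_022
sp_lipid	known_021	known_023
sp_lipid	known_021	known_024
sp_lipid	known_021	known_025
sp_lipid	known_021	known_026
sp_lipid	known_021	known_027
sp_lipid	known_021	known_028
sp_lipid	known_029	known_030
sp_lipid	known_029	known_080
sp_lipid	known_029	known_081
sp_lipid	known_029	known_082
sp_lipid	known_029	known_083
sp_lipid	known_029	known_084
sp_lipid	known_029	known_085
sp_lipid	known_021	known_029
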