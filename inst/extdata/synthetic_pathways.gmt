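sp_amino	synthetic amino-acid pathway	known_001	known_002	known_003	known_004	known_005	known_006	known_007	known_008	known_009	known_010	known_011	known_012	known_050	known_051	known_052	known_053	known_054	known_055
sp_sugar	synthetic sugar pathway	known_060	known_061	known_062	known_063	known_064	known_065	known_066	known_067	known_068	known_069	known_070	known_071	known_072	known_073	known_074	known_075
sp_lipid	synthetic lipid pathway	known_021	known_022	known_023	known_024	known_025	known_026	known_027	known_028	known_029	known_030	known_080	known_081	known_082	known_083	known_084	known_085
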