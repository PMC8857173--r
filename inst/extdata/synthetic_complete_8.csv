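compound_name,cas_rn,smiles,dtxsid,dnt_label,logd,bbb,cbrain_cblood,pgp_substrate,pgp_inhibitor,pgp_active,bdnf_label,syn_label,syn_viability,syn_ec30_um,nnf_label,nnf_viability,nnf_ec50min_um,nnf_ec50max_um
compound_001,SYN-00001-7,,DTXSYN0000001,0,1.8731208929434644,0,-0.2044206703071929,1,0,1,0,1,102.66279608536776,233.60957702385238,0,47.02995458020334,13.030898762783801,15.516740508610747
compound_002,SYN-00002-4,,DTXSYN0000002,1,3.2606001883962143,0,0.7627302668795006,0,1,1,0,1,75.92586680060154,0.6361261611573792,0,61.074437182973114,2.442959164854512,2.560679782989324
compound_003,SYN-00003-1,,DTXSYN0000003,0,1.3047758417180133,0,0.6960824814791716,1,0,0,0,1,103.37380892932052,0.7007441256655871,0,97.69400319946357,12.110426336543291,58.07122844100303
compound_004,SYN-00004-8,,DTXSYN0000004,1,1.1737474932794312,1,1.116819945464277,0,1,0,0,1,76.43975194843188,359.7867682602053,1,82.71220401985904,4.053992373461113,4.901788098335848
compound_005,SYN-00005-5,,DTXSYN0000005,0,3.1040606481579394,0,1.1685594378316346,0,0,0,0,1,99.24684323379404,22.000678180552484,1,90.20250366521162,23.52297849838568,24.549621041451342
compound_006,SYN-00006-2,,DTXSYN0000006,1,1.8381778977397727,1,0.48220436759964314,0,1,0,0,0,79.857655462671,0.09581896318738975,1,62.41529006180481,0.21572973296806328,6.654619715829331
compound_007,SYN-00007-9,,DTXSYN0000007,1,1.7445662752673448,1,1.0277140355453795,0,1,1,1,1,73.99875827511147,143.22142437581078,1,73.8324790214904,2.339882357157839,47.55609700118485
compound_008,SYN-00008-6,,DTXSYN0000008,1,0.36750243219568546,1,0.6747846090911815,0,1,1,1,1,80.32978435731813,46.487905569480496,1,83.47770561762403,13.39769270307498,23.055532418215762
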