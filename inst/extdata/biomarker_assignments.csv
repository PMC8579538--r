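wavenumber,assignment,reference
1755,lipid,ref51
1748,"C=O stretching vibration of alkyl ester, pectin",ref62
1736,C=O stretching [lipids],ref65
1735,"C=O stretching, the phenolic compound ellagic acid / the secondary metabolite quercetin",ref63
1732,lipid; fatty acid esters; hemicellulose,ref51
1728,"v (C=O) ester, cutin",ref62
1725,C=O stretching band mode of the fatty acid ester,ref65
1678,Stretching C=O vibrations that are H-bonded,ref65
1662,"Amide I, or fatty acid esters",ref65
1651,phenolic compounds / cutan [aromatic and C=C functional groups],ref62
1648,Amide I,ref65
1647,amide I; pectin,ref51
1643,C=O stretching [Amide I],ref65
1608,"aromatic ring stretch vibrations, tannins",ref61
1605,"v_as (COO-) [polysaccharides, pectin]",ref65
1586,Amide II,ref65
1546,"Amide II: [protein N-H bending, C-N stretching], alpha-helical structure",ref89
1542,Amide II,ref90
1531,Amide II,ref91
1530,"C=N adenine, cytosine",ref65
1512,v (C-C) aromatic (conjugated with C=C) phenolic compounds,ref62
1512,"v (C=C) in lignin, carotenoid or protein",ref50
1481,"symmetric deformation NH2+, glyphosate",ref60
1466,CH2 bending in lipid,ref50
1455,C-O-H,ref65
1446,"aromatic ring stretch vibrations, tannins",ref61
1445,lipids,ref63
1443,"d (CH2) [lipids, fatty acids], or d (CH) [polysaccharides, pectin]",ref65
1408,"CH3 deformation, v_s (COO-) in pectin",ref50
1405,CH3 asymmetric deformation,ref65
1397,CH3 symmetric deformation,ref65
1385,Ring stretching vibrations mixed strongly with CH in-plane bending,ref65
1161,carbohydrate; stretching vibrations of hydrogen-bonding C-OH groups; cellulose,ref51
1158,vC-O of proteins and carbohydrates,ref65
1103,v (C-O-C) in ester,ref50
1034,"C-O stretch, tannins",ref61
1015,"v (CO), v (CC), d (OCH), ring in pectin",ref50
1014,phosphodiester stretching bands [symmetrical and asymmetrical],ref65
964,"C-O deoxyribose, C-C",ref65
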