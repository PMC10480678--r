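code,name,density_g_cm3,suv
0,air,0,0
1,soft_tissue,1,0.047
2,lungs,0.3,0.1
3,liver,1.06,9.5
4,spleen,1.06,23.2
5,kidneys,1.05,9.7
6,pancreas,1.04,5.5
7,stomach_wall,1.05,7
8,bladder_contents,1,12
9,tumours,1.05,22.9
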