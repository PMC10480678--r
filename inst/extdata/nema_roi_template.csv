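ux,uy
1,0
0.866025,0.5
0.5,0.866025
0,1
-0.5,0.866025
-0.866025,0.5
-1,0
-0.866025,-0.5
-0.5,-0.866025
0,-1
0.5,-0.866025
0.866025,-0.5
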