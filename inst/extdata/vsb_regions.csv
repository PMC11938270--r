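code,name,hemisphere,group
1,ACC,ipsi,cortex
2,AH,ipsi,hypothalamus
3,BLA,ipsi,amygdala
4,BNST,ipsi,amygdala
5,CA2,ipsi,hippocampus
6,CP,ipsi,striatum
7,LS,ipsi,septum
8,MeA,ipsi,amygdala
9,mPOA,ipsi,hypothalamus
10,NAcc,ipsi,striatum
11,PAG,ipsi,midbrain
12,PVN,ipsi,hypothalamus
13,VMH,ipsi,hypothalamus
14,VP,ipsi,striatum
15,VTA,ipsi,midbrain
16,ACC,contra,cortex
17,AH,contra,hypothalamus
18,BLA,contra,amygdala
19,BNST,contra,amygdala
20,CA2,contra,hippocampus
21,CP,contra,striatum
22,LS,contra,septum
23,MeA,contra,amygdala
24,mPOA,contra,hypothalamus
25,NAcc,contra,striatum
26,PAG,contra,midbrain
27,PVN,contra,hypothalamus
28,VMH,contra,hypothalamus
29,VP,contra,striatum
30,VTA,contra,midbrain
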