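model_id,label,np,dev,mcst
1,phi(sex*t) p(m*sex*t),148,28296.6,
2,phi(sex*t) p(m*t),100,28353.1,
3,phi(sex*t) p(m),56,29609.1,
4,phi(sex*t) p(m1(.) m2(t)),77,28601.5,
5,phi(sex*t) p(m1(t) m2(.)),74,29437.2,
6,phi(sex*t) p(m+t),79,28383.6,
7,phi(t) p(m+t),53,28418.3,
8,phi(.) p(m+t),29,28553.4,
9,phi(LLccbr) p(m+t),31,28525.5,8
10,phi(LLccbr two-slope) p(m+t),32,28512.0,9
11,phi(PC1LLSSTba) p(m+t),31,28553.1,8
12,phi(PC1LLSSTba two-slope) p(m+t),32,28552.8,11
13,phi(PC2LLSSTba) p(m+t),31,28553.5,8
14,phi(PC2LLSSTba two-slope) p(m+t),32,28553.2,13
15,phi(LLccbr+SSTcc2yr) p(m+t),32,28499.7,9
16,phi(LLccbr+SSTcc2yr^2) p(m+t),33,28487.3,15
17,phi(LLccbr+SSTcc2yr two-slope) p(m+t),33,28496.6,15
18,phi(LLccbr+SOIyr) p(m+t),32,28496.1,9
19,phi(LLccbr+SOIyr^2) p(m+t),33,28485.3,18
20,phi(LLccbr+SOIyr two-slope) p(m+t),33,28486.3,18
21,phi(LLccbr+SOIw1) p(m+t),32,28525.4,9
22,phi(LLccbr+SOIw1^2) p(m+t),33,28524.1,21
23,phi(LLccbr+SOIw1 two-slope) p(m+t),33,28521.1,21
24,phi(LLccbr+SOIyr+SSTcc2yr) p(m+t),33,28486.2,18
25,phi(LLccbr+SOIyr+SSTcc2yr^2) p(m+t),34,28476.8,24
26,phi(LLccbr+SOIyr+SSTcc2yr two-slope) p(m+t),34,28484.2,24
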