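id	name
1	Left I-IV
2	Right I-IV
3	Left V
4	Right V
5	Left VI
6	Vermis VI
7	Right VI
8	Left Crus I
9	Vermis Crus I
10	Right Crus I
11	Left Crus II
12	Vermis Crus II
13	Right Crus II
14	Left VIIb
15	Vermis VIIb
16	Right VIIb
17	Left VIIIa
18	Vermis VIIIa
19	Right VIIIa
20	Left VIIIb
21	Vermis VIIIb
22	Right VIIIb
23	Left IX
24	Vermis IX
25	Right IX
26	Left X
27	Vermis X
28	Right X
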