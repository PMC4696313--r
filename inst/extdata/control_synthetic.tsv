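feature	ctrl1	ctrl2	ctrl3	ctrl4
g01	1	3	5	7
g02	2	4	6	8
g03	3	3	3	3
g04	1	2	3	4
g05	5	5	5	5
g06	4	3	2	1
g07	5	6	5	6
g08	25	26	27	25
g09	1	1	1	99
g10	12	9	6	3
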