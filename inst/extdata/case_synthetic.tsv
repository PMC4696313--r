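feature	case1	case2	case3	case4
g01	4	4	4	4
g02	2	4	6	8
g03	1	1	1	9
g04	10	20	30	40
g05	5	5	5	5
g06	1	2	3	4
g07	1	10	1	10
g08	100	1	1	1
g09	2	2	2	2
g10	3	6	9	12
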