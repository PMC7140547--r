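1	|	1	|	no rank	|
10	|	1	|	genus	|
100	|	10	|	species	|
1000	|	100	|	strain	|
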