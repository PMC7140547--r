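1	|	root	|		|	scientific name	|
10	|	Toygenus	|		|	scientific name	|
100	|	Toygenus toyspecies	|		|	scientific name	|
1000	|	Toygenus toyspecies strain T1	|		|	scientific name	|
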