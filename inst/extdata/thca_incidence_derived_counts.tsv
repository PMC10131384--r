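population	sex	cases	persons
Africa	male	41	5465978
EastAsia	male	3348	107646738
Europe	male	3024	101816542
SouthAsia	male	515	50983915
Africa	female	184	5465978
EastAsia	female	10603	107646738
Europe	female	8593	101816542
SouthAsia	female	1331	50983915
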