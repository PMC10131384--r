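gene	branch	lnl_alt	lnl_null
DROSHA	human	-9569.2	-9593.43
LY75-CD302	human	-15467	-15535
RBFOX1	human	-2118.24	-2147.37
NRG1	human	-5366.86	-5379.37
STAT3	human	-5563.45	-5577.78
NIN	human	-17468.17	-17477.49
ZNF814	human	-4723.37	-4734.49
TRAF3	human	-4022.31	-4033.59
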