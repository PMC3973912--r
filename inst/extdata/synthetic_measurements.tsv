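variable_id	aerobiosis	value	sd	kind
pyr	0	3	0.1	metabolite
pyr	25	2.1	0.1	metabolite
pyr	50	1.6	0.1	metabolite
pyr	75	1.1	0.1	metabolite
pyr	100	0.4	0.1	metabolite
pfl	0	2	0.1	transcript
pfl	25	1.7	0.1	transcript
pfl	50	1.3	0.1	transcript
pfl	75	0.9	0.1	transcript
pfl	100	0.3	0.1	transcript
ACKr	0	9.5	0.1	flux
ACKr	25	7.3	0.1	flux
ACKr	50	4.9	0.1	flux
ACKr	75	2.6	0.1	flux
ACKr	100	0.1	0.1	flux
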