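question	label
q01	0
q02	1
q03	1
q04	1
q05	0
q06	0
q07	0
q08	0
q09	0
q10	0
q11	0
q12	0
q13	1
q14	0
q15	0
q16	1
q17	0
q18	1
q19	1
q20	0
q21	0
q22	1
q23	0
q24	0
q25	0
q26	0
q27	1
q28	0
q29	0
q30	0
q31	0
q32	1
q33	0
q34	0
q35	0
q36	0
q37	1
q38	0
q39	0
q40	1
q41	0
q42	0
q43	1
q44	0
q45	0
q46	0
q47	0
q48	0
q49	1
q50	0
q51	0
q52	0
q53	1
q54	0
q55	1
q56	1
q57	0
q58	0
q59	1
q60	0
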