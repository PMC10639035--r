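index	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT	source
santalucia_dG	-1	-1.44	-1.28	-0.88	-1.45	-1.84	-2.17	-1.28	-1.3	-2.24	-1.84	-1.44	-0.58	-1.3	-1.45	-1	SantaLucia1998_unified_NN
santalucia_dH	-7.9	-8.4	-7.8	-7.2	-8.5	-8	-10.6	-7.8	-8.2	-9.8	-8	-8.4	-7.2	-8.2	-8.5	-7.9	SantaLucia1998_unified_NN
santalucia_dS	-22.2	-22.4	-21	-20.4	-22.7	-19.9	-27.2	-21	-22.2	-24.4	-19.9	-22.4	-21.3	-22.2	-22.7	-22.2	SantaLucia1998_unified_NN
gc_content	0	1	1	0	1	2	2	1	1	2	2	1	0	1	1	0	composition_by_definition
purine_content	2	1	2	1	1	0	1	0	2	1	2	1	1	0	1	0	composition_by_definition
keto_content	0	0	1	1	0	0	1	1	1	1	2	2	1	1	2	2	composition_by_definition
gc_skew	0	-1	1	0	-1	-2	0	-1	1	0	2	1	0	-1	1	0	composition_by_definition
at_skew	2	1	1	0	1	0	0	-1	1	0	0	-1	0	-1	-1	-2	composition_by_definition
count_A	2	1	1	1	1	0	0	0	1	0	0	0	1	0	0	0	composition_by_definition
count_C	0	1	0	0	1	2	1	1	0	1	0	0	0	1	0	0	composition_by_definition
count_G	0	0	1	0	0	0	1	0	1	1	2	1	0	0	1	0	composition_by_definition
count_T	0	0	0	1	0	0	0	1	0	0	0	1	1	1	1	2	composition_by_definition
first_A	1	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
first_C	0	0	0	0	1	1	1	1	0	0	0	0	0	0	0	0	composition_by_definition
first_G	0	0	0	0	0	0	0	0	1	1	1	1	0	0	0	0	composition_by_definition
first_T	0	0	0	0	0	0	0	0	0	0	0	0	1	1	1	1	composition_by_definition
second_A	1	0	0	0	1	0	0	0	1	0	0	0	1	0	0	0	composition_by_definition
second_C	0	1	0	0	0	1	0	0	0	1	0	0	0	1	0	0	composition_by_definition
second_G	0	0	1	0	0	0	1	0	0	0	1	0	0	0	1	0	composition_by_definition
second_T	0	0	0	1	0	0	0	1	0	0	0	1	0	0	0	1	composition_by_definition
homodimer	1	0	0	0	0	1	0	0	0	0	1	0	0	0	0	1	composition_by_definition
transition_step	0	0	1	0	0	0	0	1	1	0	0	0	0	1	0	0	composition_by_definition
ind_AA	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_AC	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_AG	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_AT	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_CA	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_CC	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_CG	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	0	composition_by_definition
ind_CT	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	0	composition_by_definition
ind_GA	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	0	composition_by_definition
ind_GC	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	0	composition_by_definition
ind_GG	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	0	composition_by_definition
ind_GT	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	0	composition_by_definition
ind_TA	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	0	composition_by_definition
ind_TC	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	0	composition_by_definition
ind_TG	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	0	composition_by_definition
ind_TT	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	1	composition_by_definition
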