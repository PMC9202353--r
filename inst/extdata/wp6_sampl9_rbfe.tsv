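source	target	BAR	BAR_se	BARstar	BARstar_se	fs	J_FF	J_FF_se	J_RR	J_RR_se	Js_FR	Js_FR_se	Js_RF	Js_RF_se	G_FF	G_FF_se	G_RR	G_RR_se	tanimoto	delta_volume	delta_charge	delta_n_rings
g03	g01	3.7	0.6	3.4	NA	0.0	2.6	0.8	3.8	1.6	2.0	0.7	4.3	1.3	0.5	2.0	6.5	2.0	0.55	72.01	0	-1
g04	g01	-0.4	0.6	-0.5	NA	0.0	-0.2	0.7	-0.5	1.1	-0.6	1.0	-0.1	0.7	-3.2	2.0	3.3	1.6	0.21	76.98	0	1
g12	g01	8.6	0.9	8.6	NA	-2.3	9.0	0.9	8.7	1.2	8.8	0.8	8.6	1.2	3.7	3.5	9.6	1.9	0.44	-39.90	-1	-3
g05	g02	-5.1	0.4	-5.3	NA	0.0	-3.0	0.4	-7.2	0.8	-3.2	0.6	-7.2	0.7	-4.2	0.8	NA	NA	0.53	-41.91	0	-2
g10	g02	-1.4	0.6	-1.6	NA	0.0	-0.2	1.3	-3.6	1.0	0.3	1.6	-4.2	0.6	-2.8	2.1	-0.2	1.6	0.37	12.58	0	1
g04	g03	-4.0	0.3	-4.0	NA	0.0	-4.0	1.0	-5.0	0.7	-4.3	0.5	-5.0	0.5	-5.6	1.0	-4.1	0.6	0.15	4.97	0	2
g05	g03	-1.3	0.7	-1.3	NA	-2.3	1.3	0.7	-2.2	3.3	1.5	0.7	-2.2	2.7	0.9	0.7	NA	NA	0.38	-145.55	-1	-2
g07	g03	-1.6	0.3	-1.6	NA	0.0	-2.6	2.2	-2.1	0.5	-2.5	1.8	-2.7	0.5	-3.3	1.2	-0.7	0.8	0.61	4.29	0	1
g11	g03	-2.9	0.3	-2.9	NA	0.0	-2.3	0.7	-3.7	1.0	-2.6	0.6	-3.6	0.8	-3.7	1.0	-3.0	0.7	0.40	9.54	0	2
g13	g03	-4.2	0.4	-4.2	NA	-2.3	-3.0	0.6	-5.3	0.8	-2.8	0.8	-5.5	0.6	-7.9	1.5	-3.9	1.2	0.17	-35.63	-1	0
g10	g05	3.0	0.5	3.0	NA	0.0	3.5	2.0	2.0	1.3	3.6	2.2	1.9	1.2	NA	NA	2.4	0.8	0.34	54.48	-1	3
g11	g06	-2.9	0.3	-2.8	NA	0.0	-1.8	1.0	-3.2	1.2	-1.6	1.1	-3.1	1.0	-3.9	1.1	-2.5	1.1	0.50	30.97	0	1
g12	g06	6.4	0.3	6.4	NA	-2.3	7.7	0.5	5.8	0.9	7.9	0.4	5.6	1.1	5.8	0.9	7.6	1.2	0.43	-90.48	-1	-3
g08	g07	-3.1	0.8	-3.5	NA	2.0	-3.4	2.7	-3.6	1.3	-1.2	2.2	-6.0	1.8	-4.7	2.1	2.9	3.4	0.21	-77.36	1	0
g10	g07	2.7	0.4	2.6	NA	-2.3	4.8	0.9	0.0	0.6	4.8	1.1	0.0	0.4	3.2	1.1	4.6	1.6	0.24	-95.36	-1	0
g09	g08	4.3	0.8	4.3	NA	-2.0	4.6	1.7	3.8	1.2	6.2	1.1	1.5	2.1	2.1	2.0	6.9	2.0	0.22	35.17	-1	-3
g10	g08	5.7	0.9	5.8	NA	-4.3	7.2	1.2	4.6	2.1	8.3	1.4	3.2	2.0	4.4	1.7	6.4	2.3	0.80	-18.00	-2	0
g12	g11	9.2	0.4	9.2	NA	-2.3	10.2	0.6	9.2	0.8	10.1	0.6	9.3	0.7	9.0	0.9	11.0	1.7	0.29	-121.45	-1	-4
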