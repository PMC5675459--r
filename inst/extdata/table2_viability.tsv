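cell_line	drugs	viability	ste	interaction	ci_low	ci_high	label
H1299	CPT	0.77	0.01				
H1299	CisPt	0.82	0.01				
H1299	CbPt	0.77	0.01				
H1299	NCZ	0.73	0.02				
H1299	MG132	0.68	0.02				
H1299	Etopo	0.72	0.01				
H1299	CPT+CisPt	0.67	0.02	0.04	0.01	0.08	antagonistic
H1299	CPT+CbPt	0.58	0.02	-0.01	-0.05	0.02	additive
H1299	CPT+NCZ	0.66	0.02	0.07	0.04	0.09	antagonistic
H1299	CPT+MG132	0.66	0.01	0.12	0.09	0.15	antagonistic
H1299	CPT+Etopo	0.51	0.01	-0.05	-0.08	-0.02	synergistic
H1299	CisPt+CbPt	0.73	0.02	0.08	0.05	0.11	antagonistic
H1299	CisPt+NCZ	0.72	0.02	0.10	0.07	0.12	antagonistic
H1299	CisPt+MG132	0.74	0.02	0.15	0.12	0.18	antagonistic
H1299	CisPt+Etopo	0.68	0.02	0.08	0.06	0.11	antagonistic
H1299	CbPt+NCZ	0.41	0.02	-0.17	-0.23	-0.11	synergistic
H1299	CbPt+MG132	0.58	0.02	0.06	0.03	0.09	antagonistic
H1299	CbPt+Etopo	0.64	0.02	0.08	0.06	0.11	antagonistic
H1299	NCZ+MG132	0.47	0.02	-0.04	-0.08	-0.01	synergistic
H1299	NCZ+Etopo	0.78	0.02	0.23	0.20	0.25	antagonistic
H1299	MG132+Etopo	0.72	0.02	0.21	0.18	0.24	antagonistic
H1299	CPT+CisPt+CbPt	0.37	0.04	-0.07	-0.13	-0.01	synergistic
H1299	CPT+CisPt+NCZ	0.31	0.03	-0.16	-0.26	-0.07	synergistic
H1299	CPT+CisPt+MG132	0.37	0.01	-0.04	-0.10	0.02	additive
H1299	CPT+CisPt+Etopo	0.40	0.04	-0.03	-0.12	0.07	additive
H1299	CPT+CbPt+NCZ	0.53	0.01	0.05	-0.01	0.12	additive
H1299	CPT+CbPt+MG132	0.31	0.02	-0.06	-0.13	0.00	synergistic
H1299	CPT+CbPt+Etopo	0.32	0.03	-0.08	-0.20	0.04	additive
H1299	CPT+NCZ+MG132	0.28	0.05	-0.11	-0.18	-0.05	synergistic
H1299	CPT+NCZ+Etopo	0.34	0.00	-0.08	-0.14	-0.02	synergistic
H1299	CPT+MG132+Etopo	0.58	0.03	0.14	0.05	0.25	antagonistic
H1299	CisPt+CbPt+NCZ	0.18	0.01	-0.35	-0.45	-0.26	synergistic
H1299	CisPt+CbPt+MG132	0.55	0.01	0.08	-0.02	0.17	additive
H1299	CisPt+CbPt+Etopo	0.52	0.02	0.02	-0.03	0.07	additive
H1299	CisPt+NCZ+MG132	0.22	0.01	-0.25	-0.42	-0.10	synergistic
H1299	CisPt+NCZ+Etopo	0.68	0.01	0.20	0.15	0.25	antagonistic
H1299	CisPt+MG132+Etopo	0.72	0.01	0.26	0.21	0.31	antagonistic
H1299	CbPt+NCZ+MG132	0.15	0.01	-0.30	-0.51	-0.14	synergistic
H1299	CbPt+NCZ+Etopo	0.29	0.01	-0.05	-0.12	0.02	additive
H1299	CbPt+MG132+Etopo	0.50	0.01	0.17	0.12	0.23	antagonistic
H1299	NCZ+MG132+Etopo	0.30	0.01	0.02	-0.01	0.05	additive
H1299	CPT+CisPt+CbPt+NCZ	0.14	0.00	-0.15	-0.21	-0.10	synergistic
H1299	CPT+CisPt+CbPt+MG132	0.19	0.01	-0.07	-0.14	0.00	additive
H1299	CPT+CisPt+CbPt+Etopo	0.10	0.02	-0.22	-0.28	-0.15	synergistic
H1299	CPT+CisPt+NCZ+MG132	0.17	0.01	-0.06	-0.11	-0.01	synergistic
H1299	CPT+CisPt+NCZ+Etopo	0.15	0.01	-0.13	-0.17	-0.09	synergistic
H1299	CPT+CisPt+MG132+Etopo	0.16	0.01	-0.09	-0.15	-0.02	synergistic
H1299	CPT+CbPt+NCZ+MG132	0.16	0.00	-0.14	-0.23	-0.07	synergistic
H1299	CPT+CbPt+NCZ+Etopo	0.14	0.01	-0.22	-0.28	-0.15	synergistic
H1299	CPT+CbPt+MG132+Etopo	0.25	0.01	-0.03	-0.09	0.03	additive
H1299	CPT+NCZ+MG132+Etopo	0.21	0.01	-0.08	-0.12	-0.04	synergistic
H1299	CisPt+CbPt+NCZ+MG132	0.10	0.00	-0.24	-0.32	-0.16	synergistic
H1299	CisPt+CbPt+NCZ+Etopo	0.21	0.01	-0.10	-0.17	-0.03	synergistic
H1299	CisPt+CbPt+MG132+Etopo	0.55	0.01	0.22	0.19	0.26	antagonistic
H1299	CisPt+NCZ+MG132+Etopo	0.37	0.01	0.08	0.03	0.13	antagonistic
H1299	CbPt+NCZ+MG132+Etopo	0.11	0.01	-0.20	-0.25	-0.14	synergistic
H1299	CPT+CisPt+CbPt+NCZ+MG132	0.22	0.04	-0.19	-0.27	-0.11	synergistic
H1299	CPT+CisPt+CbPt+NCZ+Etopo	0.27	0.02	0.00	-0.06	0.05	additive
H1299	CPT+CisPt+CbPt+MG132+Etopo	0.43	0.01	0.06	0.00	0.13	antagonistic
H1299	CPT+CisPt+NCZ+MG132+Etopo	0.26	0.01	0.01	-0.06	0.08	additive
H1299	CPT+CbPt+NCZ+MG132+Etopo	0.17	0.03	-0.15	-0.25	-0.06	synergistic
H1299	CisPt+CbPt+NCZ+MG132+Etopo	0.20	0.01	-0.09	-0.14	-0.03	synergistic
H1299	CPT+CisPt+CbPt+NCZ+MG132+Etopo	0.29	0.03	0.04	-0.01	0.09	additive
HeLa	CPT	0.73	0.02				
HeLa	CisPt	0.65	0.03				
HeLa	CbPt	0.27	0.04				
HeLa	NCZ	0.83	0.02				
HeLa	MG132	0.70	0.02				
HeLa	Etopo	0.71	0.02				
HeLa	CPT+CisPt	0.62	0.02	0.13	0.10	0.16	antagonistic
HeLa	CPT+CbPt	0.09	0.01	-0.14	-0.19	-0.09	synergistic
HeLa	CPT+NCZ	0.66	0.03	0.10	0.07	0.13	antagonistic
HeLa	CPT+MG132	0.76	0.02	0.21	0.17	0.24	antagonistic
HeLa	CPT+Etopo	0.60	0.02	0.07	0.04	0.10	antagonistic
HeLa	CisPt+CbPt	0.11	0.02	-0.07	-0.09	-0.05	synergistic
HeLa	CisPt+NCZ	0.87	0.04	0.24	0.19	0.29	antagonistic
HeLa	CisPt+MG132	0.80	0.03	0.28	0.24	0.32	antagonistic
HeLa	CisPt+Etopo	0.63	0.01	0.15	0.11	0.18	antagonistic
HeLa	CbPt+MG132	0.25	0.03	0.05	0.03	0.07	antagonistic
HeLa	CbPt+Etopo	0.17	0.01	-0.02	-0.06	0.01	additive
HeLa	NCZ+MG132	0.78	0.02	0.15	0.11	0.19	antagonistic
HeLa	NCZ+Etopo	0.77	0.03	0.18	0.13	0.22	antagonistic
HeLa	MG132+Etopo	0.83	0.02	0.28	0.23	0.32	antagonistic
HeLa	CPT+CisPt+CbPt	0.08	0.00	-0.07	-0.10	-0.04	synergistic
HeLa	CPT+CisPt+NCZ	0.60	0.02	0.19	0.13	0.23	antagonistic
HeLa	CPT+CisPt+MG132	0.55	0.01	0.18	0.14	0.22	antagonistic
HeLa	CPT+CisPt+Etopo	0.41	0.01	0.06	0.03	0.09	antagonistic
HeLa	CPT+CbPt+MG132	0.08	0.04	-0.07	-0.09	-0.05	synergistic
HeLa	CPT+CbPt+Etopo	0.02	0.00	-0.14	-0.19	-0.10	synergistic
HeLa	CPT+NCZ+MG132	0.63	0.02	0.19	0.17	0.22	antagonistic
HeLa	CPT+NCZ+Etopo	0.54	0.00	0.14	0.10	0.19	antagonistic
HeLa	CPT+MG132+Etopo	0.64	0.01	0.22	0.16	0.27	antagonistic
HeLa	CisPt+CbPt+MG132	0.10	0.00	-0.04	-0.06	-0.01	synergistic
HeLa	CisPt+CbPt+Etopo	0.07	0.01	-0.07	-0.09	-0.04	synergistic
HeLa	CisPt+NCZ+MG132	0.74	0.02	0.26	0.23	0.30	antagonistic
HeLa	CisPt+NCZ+Etopo	0.64	0.01	0.20	0.17	0.24	antagonistic
HeLa	CisPt+MG132+Etopo	0.61	0.01	0.24	0.21	0.27	antagonistic
HeLa	CbPt+MG132+Etopo	0.19	0.00	0.05	0.02	0.07	antagonistic
HeLa	NCZ+MG132+Etopo	0.71	0.02	0.25	0.20	0.30	antagonistic
HeLa	CPT+CisPt+CbPt+MG132	0.03	0.00	-0.09	-0.13	-0.05	synergistic
HeLa	CPT+CisPt+CbPt+Etopo	0.02	0.00	-0.09	-0.11	-0.06	synergistic
HeLa	CPT+CisPt+NCZ+MG132	0.48	0.02	0.17	0.14	0.20	antagonistic
HeLa	CPT+CisPt+NCZ+Etopo	0.41	0.01	0.12	0.09	0.16	antagonistic
HeLa	CPT+CbPt+MG132+Etopo	0.03	0.00	-0.06	-0.09	-0.03	synergistic
HeLa	CPT+NCZ+MG132+Etopo	0.77	0.02	0.40	0.37	0.42	antagonistic
HeLa	CisPt+CbPt+MG132+Etopo	0.04	0.01	-0.06	-0.09	-0.04	synergistic
HeLa	CisPt+NCZ+MG132+Etopo	0.80	0.01	0.40	0.37	0.43	antagonistic
HeLa	CPT+CisPt+CbPt+MG132+Etopo	0.00	0.00	-0.06	-0.08	-0.04	synergistic
HeLa	CPT+CisPt+NCZ+MG132+Etopo	0.58	0.01	0.32	0.30	0.34	antagonistic
HeLa	CbPt+NCZ	-	-	-	-	-	
HeLa	CPT+CbPt+NCZ	-	-	-	-	-	
HeLa	CisPt+CbPt+NCZ	-	-	-	-	-	
HeLa	CbPt+NCZ+MG132	-	-	-	-	-	
HeLa	CbPt+NCZ+Etopo	-	-	-	-	-	
HeLa	CPT+CisPt+CbPt+NCZ	-	-	-	-	-	
HeLa	CPT+CisPt+MG132+Etopo	-	-	-	-	-	
HeLa	CPT+CbPt+NCZ+MG132	-	-	-	-	-	
HeLa	CPT+CbPt+NCZ+Etopo	-	-	-	-	-	
HeLa	CisPt+CbPt+NCZ+MG132	-	-	-	-	-	
HeLa	CisPt+CbPt+NCZ+Etopo	-	-	-	-	-	
HeLa	CbPt+NCZ+MG132+Etopo	-	-	-	-	-	
HeLa	CPT+CisPt+CbPt+NCZ+MG132	-	-	-	-	-	
HeLa	CPT+CisPt+CbPt+NCZ+Etopo	-	-	-	-	-	
HeLa	CPT+CbPt+NCZ+MG132+Etopo	-	-	-	-	-	
HeLa	CisPt+CbPt+NCZ+MG132+Etopo	-	-	-	-	-	
HeLa	CPT+CisPt+CbPt+NCZ+MG132+Etopo	-	-	-	-	-	
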