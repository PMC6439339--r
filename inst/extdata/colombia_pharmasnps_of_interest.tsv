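rsid	drug_response	freq_antioquia	freq_choco	beta_afr	p_afr	beta_eur	p_eur	beta_nam	p_nam	flagged
rs776746	Tacrolimus metabolism	0.81	0.32	0.31	4.00e-22	-0.24	2.20e-21	-0.06	1.10e-08	*
rs1799853	Warfarin dosage	0.88	0.97	-0.25	4.20e-04	0.21	2.50e-04	0.04	8.40e-02	.
rs9923231	Warfarin dosage	0.57	0.88	0.24	1.00e-10	-0.19	1.00e-10	-0.04	2.90e-04	*
rs4149056	Simvastatin toxicity	0.18	0.05	-0.22	2.80e-04	0.18	1.80e-04	0.00	6.20e-02	*
rs4244285	Clopidogrel efficacy	0.90	0.84	0.09	1.36e-01	-0.06	1.87e-01	-0.02	1.67e-01	.
rs2740574	Tacrolimus metabolism	0.10	0.59	0.32	1.20e-22	-0.24	2.20e-21	-0.06	1.00e-09	.
rs11615	Platin toxicity	0.48	0.07	-0.30	9.80e-18	0.25	2.50e-19	0.04	1.10e-04	.
rs11212617	Metformin efficacy	0.33	0.74	0.28	5.30e-16	-0.21	8.30e-15	-0.06	2.70e-07	.
rs6977820	Antipsychotic drug toxicity	0.25	0.68	0.28	5.30e-16	-0.19	1.70e-12	-0.07	1.20e-11	.
rs3812718	Antiepileptic treatment resistance	0.55	0.27	-0.27	2.00e-06	0.21	8.40e-06	0.05	7.74e-04	.
rs7793837	Salbutamol efficacy	0.69	0.24	0.21	4.30e-17	0.21	2.90e-16	0.05	2.80e-07	.
rs1954787	Antidepressant efficacy	0.62	0.21	-0.24	3.00e-13	0.18	6.80e-12	0.05	4.20e-07	.
rs1719247	Simvastatin adverse reaction	0.54	0.27	-0.21	3.90e-08	0.17	3.50e-08	0.04	2.00e-03	.
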