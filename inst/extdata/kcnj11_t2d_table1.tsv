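study_id	year	ethnicity	design	n_cases	n_controls	maf_cases	maf_controls	ee_cases	ek_cases	kk_cases	ee_controls	ek_controls	kk_controls	n_trios	transmitted	untransmitted	bmi_cases	bmi_controls	age_cases	age_controls	pct_male_cases	pct_male_controls	hwe_p
Sakura_1996	1996	Caucasian	population	133	82	0.30	0.30	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.05
Inoue_1997	1997	Caucasian	population	291	164	0.34	0.34	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Hani_1998	1998	Caucasian	population	191	114	0.49	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.95
Altshuler_2000	2000	Caucasian	family	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	333	NA	NA	NA	NA	NA	NA	NA	NA	NA
Yamada_2001	2001	East Asian	population	103	73	0.39	0.34	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.20
Gloyn_2001	2001	Caucasian	population	360	307	0.40	0.36	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.09
Florez_2004	2004	Caucasian	population	1077	1077	0.47	0.61	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.71
Barroso_2003	2003	Caucasian	population	499	494	0.38	0.34	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.82
Gloyn_2003	2003	Caucasian	both	854	1182	0.41	0.34	NA	NA	NA	NA	NA	NA	150	NA	NA	NA	NA	NA	NA	NA	NA	0.53
Hansen_2005	2005	Caucasian	population	1164	4733	0.40	0.36	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.52
vanDam_2005	2005	Caucasian	population	323	296	0.41	0.36	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.56
Yokoi_2006	2006	East Asian	population	1590	1244	0.38	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.64
Liu_2006	2006	East Asian	population	502	501	0.43	0.38	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Weedon_2006	2006	Caucasian	population	2332	3592	0.38	0.35	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Sale_2007	2007	Other	population	572	587	0.06	0.07	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.22
Koo_2007	2007	East Asian	population	758	630	0.44	0.38	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.05
Sakamoto_2007	2007	East Asian	population	906	889	0.39	0.34	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.72
Saxena_2007	2007	Caucasian	population	5065	5785	0.49	0.47	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Vaxillaire_2007	2007	Caucasian	population	287	2684	0.41	0.39	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.68
Scott_2007	2007	Caucasian	population	2295	2363	0.49	0.46	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.72
Willer_2007	2007	Caucasian	population	1087	953	0.49	0.44	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.32
Qi_2007	2007	Caucasian	population	682	1078	0.40	0.35	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.38
Cejkova_2007	2007	Caucasian	population	172	113	0.37	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.26
Doi_2007	2007	East Asian	population	550	2322	0.39	0.34	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.46
Lyssenko_2008	2008	Caucasian	population	2201	16034	0.41	0.40	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Alsmadi_2008	2008	Other	population	550	335	0.21	0.14	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.40
Takeuchi_2008	2008	East Asian	population	7954	8809	0.38	0.35	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.91
Peng_2008	2008	East Asian	population	275	168	0.69	0.57	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Bronstein_2008	2008	Other	population	1131	1147	0.36	0.61	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.58
Sanghera_2008	2008	Indian	population	532	374	0.34	0.38	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.45
Cauchi_2008	2008	Caucasian	population	2734	4234	0.37	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.69
Ezzidi_2009	2009	Other	population	805	503	0.32	0.29	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.56
Zhou_2009	2009	East Asian	population	1848	1910	0.41	0.39	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.39
Chistiakov_2009	2009	Caucasian	population	129	117	0.50	0.39	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Wang_2009	2009	East Asian	population	396	387	0.46	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.46
Tabara_2009	2009	East Asian	population	484	397	0.41	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.30
Thorsby_2009	2009	Caucasian	population	750	1879	0.41	0.41	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.18
Hu_2009	2009	East Asian	population	1849	1785	0.42	0.39	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Yamauchi_2010	2010	East Asian	population	4470	3071	0.38	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Neuman_2010	2010	Other	population	573	843	0.37	0.36	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.22
Chauhan_2010	2010	Indian	population	2434	2403	0.39	0.32	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.41
Gupta_2010	2010	Indian	population	209	179	0.40	0.47	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.12
Wen_2010	2010	East Asian	population	1165	1135	0.41	0.40	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.10
Rees_2011	2011	Indian	population	1663	1567	0.38	0.38	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.13
Chavali_2011	2011	Indian	population	1017	1006	0.39	0.35	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Cheung_2011	2011	Chinese	population	198	1185	0.33	0.33	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	0.41
GamboaMelendez_2012	2012	Other	population	1027	990	0.40	0.37	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	>0.05
Gonen_2012	2012	Other	population	162	79	0.34	0.30	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA
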