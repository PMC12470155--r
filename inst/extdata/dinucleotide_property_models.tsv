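id	name	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT	units	source
1	Twist	38.90	31.12	32.15	33.81	41.41	34.96	32.91	32.15	41.31	38.50	34.96	31.12	33.28	41.31	41.41	38.90	deg	synthetic fixture, literature-typical magnitudes
3	Rise	3.27	3.36	3.34	3.31	3.33	3.42	3.39	3.34	3.37	3.40	3.42	3.36	3.42	3.37	3.33	3.27	angstrom	synthetic fixture, literature-typical magnitudes
15	Persistence Length	50.4	44.7	54.4	40.9	46.7	51.6	56.0	54.4	48.8	44.1	51.6	44.7	40.3	48.8	46.7	50.4	nm	synthetic fixture, literature-typical magnitudes
28	Slide	-0.03	-0.13	0.47	-0.37	1.46	0.60	0.63	0.47	-0.07	0.29	0.60	-0.13	0.74	-0.07	1.46	-0.03	angstrom	synthetic fixture, literature-typical magnitudes
30	Shift	0.06	-0.04	0.07	0.00	0.11	0.03	0.00	-0.07	-0.02	0.00	-0.03	0.04	0.00	0.02	-0.11	-0.06	angstrom	synthetic fixture, literature-typical magnitudes
62	Tilt	-1.40	-0.50	-2.70	0.00	0.50	-0.10	0.00	2.70	-1.70	0.00	0.10	0.50	0.00	1.70	-0.50	1.40	deg	synthetic fixture, literature-typical magnitudes
63	Roll	0.9	0.8	4.6	-0.8	4.9	5.8	3.9	4.6	3.6	0.5	5.8	0.8	6.2	3.6	4.9	0.9	deg	synthetic fixture, literature-typical magnitudes
67	Slide stiffness	2.26	3.03	2.03	3.83	1.78	1.65	2.00	2.03	1.93	2.61	1.65	3.03	1.20	1.93	1.78	2.26	kcal/mol/A^2	synthetic fixture, literature-typical magnitudes
71	Twist stiffness	0.026	0.036	0.031	0.033	0.016	0.026	0.014	0.031	0.025	0.025	0.026	0.036	0.017	0.025	0.016	0.026	kcal/mol/deg^2	synthetic fixture, literature-typical magnitudes
88	Twist	35.10	31.50	31.90	29.30	37.30	32.90	36.10	31.90	36.30	33.60	32.90	31.50	37.80	36.30	37.30	35.10	deg	synthetic fixture, literature-typical magnitudes
90	Roll	0.2	0.3	5.3	-1.6	5.5	6.6	4.7	5.3	4.4	-0.6	6.6	0.3	7.4	4.4	5.5	0.2	deg	synthetic fixture, literature-typical magnitudes
92	Twist	35.60	34.40	27.70	31.50	34.50	33.70	29.80	27.70	36.90	40.00	33.70	34.40	36.00	36.90	34.50	35.60	deg	synthetic fixture, literature-typical magnitudes
94	Roll	0.6	0.4	4.9	-1.2	5.1	6.1	4.3	4.9	4.0	-0.1	6.1	0.4	6.8	4.0	5.1	0.6	deg	synthetic fixture, literature-typical magnitudes
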