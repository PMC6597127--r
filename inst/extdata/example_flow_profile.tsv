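time_s	flow_L_per_s
0	0
0.02	0.019272
0.04	0.038514
0.06	0.057696
0.08	0.07679
0.1	0.095765
0.12	0.114592
0.14	0.133243
0.16	0.151688
0.18	0.1699
0.2	0.187849
0.22	0.205509
0.24	0.222852
0.26	0.239851
0.28	0.256481
0.3	0.272715
0.32	0.288528
0.34	0.303897
0.36	0.318797
0.38	0.333206
0.4	0.3471
0.42	0.36046
0.44	0.373263
0.46	0.385492
0.48	0.397125
0.5	0.408147
0.52	0.418539
0.54	0.428285
0.56	0.437372
0.58	0.445784
0.6	0.453508
0.62	0.460534
0.64	0.466849
0.66	0.472444
0.68	0.477311
0.7	0.481442
0.72	0.48483
0.74	0.487471
0.76	0.489361
0.78	0.490495
0.8	0.490874
0.82	0.490495
0.84	0.489361
0.86	0.487471
0.88	0.48483
0.9	0.481442
0.92	0.477311
0.94	0.472444
0.96	0.466849
0.98	0.460534
1	0.453508
1.02	0.445784
1.04	0.437372
1.06	0.428285
1.08	0.418539
1.1	0.408147
1.12	0.397125
1.14	0.385492
1.16	0.373263
1.18	0.36046
1.2	0.3471
1.22	0.333206
1.24	0.318797
1.26	0.303897
1.28	0.288528
1.3	0.272715
1.32	0.256481
1.34	0.239851
1.36	0.222852
1.38	0.205509
1.4	0.187849
1.42	0.1699
1.44	0.151688
1.46	0.133243
1.48	0.114592
1.5	0.095765
1.52	0.07679
1.54	0.057696
1.56	0.038514
1.58	0.019272
1.6	0
1.62	-0.019272
1.64	-0.038514
1.66	-0.057696
1.68	-0.07679
1.7	-0.095765
1.72	-0.114592
1.74	-0.133243
1.76	-0.151688
1.78	-0.1699
1.8	-0.187849
1.82	-0.205509
1.84	-0.222852
1.86	-0.239851
1.88	-0.256481
1.9	-0.272715
1.92	-0.288528
1.94	-0.303897
1.96	-0.318797
1.98	-0.333206
2	-0.3471
2.02	-0.36046
2.04	-0.373263
2.06	-0.385492
2.08	-0.397125
2.1	-0.408147
2.12	-0.418539
2.14	-0.428285
2.16	-0.437372
2.18	-0.445784
2.2	-0.453508
2.22	-0.460534
2.24	-0.466849
2.26	-0.472444
2.28	-0.477311
2.3	-0.481442
2.32	-0.48483
2.34	-0.487471
2.36	-0.489361
2.38	-0.490495
2.4	-0.490874
2.42	-0.490495
2.44	-0.489361
2.46	-0.487471
2.48	-0.48483
2.5	-0.481442
2.52	-0.477311
2.54	-0.472444
2.56	-0.466849
2.58	-0.460534
2.6	-0.453508
2.62	-0.445784
2.64	-0.437372
2.66	-0.428285
2.68	-0.418539
2.7	-0.408147
2.72	-0.397125
2.74	-0.385492
2.76	-0.373263
2.78	-0.36046
2.8	-0.3471
2.82	-0.333206
2.84	-0.318797
2.86	-0.303897
2.88	-0.288528
2.9	-0.272715
2.92	-0.256481
2.94	-0.239851
2.96	-0.222852
2.98	-0.205509
3	-0.187849
3.02	-0.1699
3.04	-0.151688
3.06	-0.133243
3.08	-0.114592
3.1	-0.095765
3.12	-0.07679
3.14	-0.057696
3.16	-0.038514
3.18	-0.019272
3.2	0
3.22	0.019272
3.24	0.038514
3.26	0.057696
3.28	0.07679
3.3	0.095765
3.32	0.114592
3.34	0.133243
3.36	0.151688
3.38	0.1699
3.4	0.187849
3.42	0.205509
3.44	0.222852
3.46	0.239851
3.48	0.256481
3.5	0.272715
3.52	0.288528
3.54	0.303897
3.56	0.318797
3.58	0.333206
3.6	0.3471
3.62	0.36046
3.64	0.373263
3.66	0.385492
3.68	0.397125
3.7	0.408147
3.72	0.418539
3.74	0.428285
3.76	0.437372
3.78	0.445784
3.8	0.453508
3.82	0.460534
3.84	0.466849
3.86	0.472444
3.88	0.477311
3.9	0.481442
3.92	0.48483
3.94	0.487471
3.96	0.489361
3.98	0.490495
4	0.490874
4.02	0.490495
4.04	0.489361
4.06	0.487471
4.08	0.48483
4.1	0.481442
4.12	0.477311
4.14	0.472444
4.16	0.466849
4.18	0.460534
4.2	0.453508
4.22	0.445784
4.24	0.437372
4.26	0.428285
4.28	0.418539
4.3	0.408147
4.32	0.397125
4.34	0.385492
4.36	0.373263
4.38	0.36046
4.4	0.3471
4.42	0.333206
4.44	0.318797
4.46	0.303897
4.48	0.288528
4.5	0.272715
4.52	0.256481
4.54	0.239851
4.56	0.222852
4.58	0.205509
4.6	0.187849
4.62	0.1699
4.64	0.151688
4.66	0.133243
4.68	0.114592
4.7	0.095765
4.72	0.07679
4.74	0.057696
4.76	0.038514
4.78	0.019272
4.8	0
4.82	-0.019272
4.84	-0.038514
4.86	-0.057696
4.88	-0.07679
4.9	-0.095765
4.92	-0.114592
4.94	-0.133243
4.96	-0.151688
4.98	-0.1699
5	-0.187849
5.02	-0.205509
5.04	-0.222852
5.06	-0.239851
5.08	-0.256481
5.1	-0.272715
5.12	-0.288528
5.14	-0.303897
5.16	-0.318797
5.18	-0.333206
5.2	-0.3471
5.22	-0.36046
5.24	-0.373263
5.26	-0.385492
5.28	-0.397125
5.3	-0.408147
5.32	-0.418539
5.34	-0.428285
5.36	-0.437372
5.38	-0.445784
5.4	-0.453508
5.42	-0.460534
5.44	-0.466849
5.46	-0.472444
5.48	-0.477311
5.5	-0.481442
5.52	-0.48483
5.54	-0.487471
5.56	-0.489361
5.58	-0.490495
5.6	-0.490874
5.62	-0.490495
5.64	-0.489361
5.66	-0.487471
5.68	-0.48483
5.7	-0.481442
5.72	-0.477311
5.74	-0.472444
5.76	-0.466849
5.78	-0.460534
5.8	-0.453508
5.82	-0.445784
5.84	-0.437372
5.86	-0.428285
5.88	-0.418539
5.9	-0.408147
5.92	-0.397125
5.94	-0.385492
5.96	-0.373263
5.98	-0.36046
6	-0.3471
6.02	-0.333206
6.04	-0.318797
6.06	-0.303897
6.08	-0.288528
6.1	-0.272715
6.12	-0.256481
6.14	-0.239851
6.16	-0.222852
6.18	-0.205509
6.2	-0.187849
6.22	-0.1699
6.24	-0.151688
6.26	-0.133243
6.28	-0.114592
6.3	-0.095765
6.32	-0.07679
6.34	-0.057696
6.36	-0.038514
6.38	-0.019272
6.4	0
6.42	0.019272
6.44	0.038514
6.46	0.057696
6.48	0.07679
6.5	0.095765
6.52	0.114592
6.54	0.133243
6.56	0.151688
6.58	0.1699
6.6	0.187849
6.62	0.205509
6.64	0.222852
6.66	0.239851
6.68	0.256481
6.7	0.272715
6.72	0.288528
6.74	0.303897
6.76	0.318797
6.78	0.333206
6.8	0.3471
6.82	0.36046
6.84	0.373263
6.86	0.385492
6.88	0.397125
6.9	0.408147
6.92	0.418539
6.94	0.428285
6.96	0.437372
6.98	0.445784
7	0.453508
7.02	0.460534
7.04	0.466849
7.06	0.472444
7.08	0.477311
7.1	0.481442
7.12	0.48483
7.14	0.487471
7.16	0.489361
7.18	0.490495
7.2	0.490874
7.22	0.490495
7.24	0.489361
7.26	0.487471
7.28	0.48483
7.3	0.481442
7.32	0.477311
7.34	0.472444
7.36	0.466849
7.38	0.460534
7.4	0.453508
7.42	0.445784
7.44	0.437372
7.46	0.428285
7.48	0.418539
7.5	0.408147
7.52	0.397125
7.54	0.385492
7.56	0.373263
7.58	0.36046
7.6	0.3471
7.62	0.333206
7.64	0.318797
7.66	0.303897
7.68	0.288528
7.7	0.272715
7.72	0.256481
7.74	0.239851
7.76	0.222852
7.78	0.205509
7.8	0.187849
7.82	0.1699
7.84	0.151688
7.86	0.133243
7.88	0.114592
7.9	0.095765
7.92	0.07679
7.94	0.057696
7.96	0.038514
7.98	0.019272
8	0
8.02	-0.019272
8.04	-0.038514
8.06	-0.057696
8.08	-0.07679
8.1	-0.095765
8.12	-0.114592
8.14	-0.133243
8.16	-0.151688
8.18	-0.1699
8.2	-0.187849
8.22	-0.205509
8.24	-0.222852
8.26	-0.239851
8.28	-0.256481
8.3	-0.272715
8.32	-0.288528
8.34	-0.303897
8.36	-0.318797
8.38	-0.333206
8.4	-0.3471
8.42	-0.36046
8.44	-0.373263
8.46	-0.385492
8.48	-0.397125
8.5	-0.408147
8.52	-0.418539
8.54	-0.428285
8.56	-0.437372
8.58	-0.445784
8.6	-0.453508
8.62	-0.460534
8.64	-0.466849
8.66	-0.472444
8.68	-0.477311
8.7	-0.481442
8.72	-0.48483
8.74	-0.487471
8.76	-0.489361
8.78	-0.490495
8.8	-0.490874
8.82	-0.490495
8.84	-0.489361
8.86	-0.487471
8.88	-0.48483
8.9	-0.481442
8.92	-0.477311
8.94	-0.472444
8.96	-0.466849
8.98	-0.460534
9	-0.453508
9.02	-0.445784
9.04	-0.437372
9.06	-0.428285
9.08	-0.418539
9.1	-0.408147
9.12	-0.397125
9.14	-0.385492
9.16	-0.373263
9.18	-0.36046
9.2	-0.3471
9.22	-0.333206
9.24	-0.318797
9.26	-0.303897
9.28	-0.288528
9.3	-0.272715
9.32	-0.256481
9.34	-0.239851
9.36	-0.222852
9.38	-0.205509
9.4	-0.187849
9.42	-0.1699
9.44	-0.151688
9.46	-0.133243
9.48	-0.114592
9.5	-0.095765
9.52	-0.07679
9.54	-0.057696
9.56	-0.038514
9.58	-0.019272
9.6	0
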