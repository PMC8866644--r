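patient	session	AQ	LQ	speech	repetition	reading	comprehension	naming	writing
1	T0	52.0	53.9	13	16	59	142	43	45
2	T0	27.6	25.0	7	16	45	89	7	18
3	T0	97.6	98.4	19.5	100	100	197	94	99
4	T0	47.8	40.1	8	60	29	96	51	28
5	T0	63.6	57.1	14.5	22	54	146	78	36
1	T1	56.8	58.4	NA	NA	NA	NA	NA	NA
2	T1	34.4	33.1	NA	NA	NA	NA	NA	NA
3	T1	99.0	99.5	NA	NA	NA	NA	NA	NA
4	T1	56.4	51.7	NA	NA	NA	NA	NA	NA
5	T1	67.0	61.6	NA	NA	NA	NA	NA	NA
1	T2	55.6	57.8	NA	NA	NA	NA	NA	NA
2	T2	38.4	35.4	NA	NA	NA	NA	NA	NA
3	T2	99.0	99.5	NA	NA	NA	NA	NA	NA
4	T2	55.6	50.1	NA	NA	NA	NA	NA	NA
5	T2	59.0	54.3	NA	NA	NA	NA	NA	NA
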