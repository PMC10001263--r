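hp_id	haplotype	count	freq_pct	n_dogs	n_homozygous	n_breeds	predominant_breed	predominant_pct
12	88*004:02|12*001:01:01|DRB1*006:01	68	4.23	60	8	10	NA	NA
20	88*003:02|88L*017:01|DRB1*002:01	64	3.99	45	19	6	Shetland Sheepdog	73.4
31	88*003:02|88L*017:01|DRB1*009:01	64	3.99	59	5	11	NA	NA
25	88*028:01|88L*029:01|DRB1*015:02	62	3.86	52	10	8	NA	NA
8	88*501:01|12*001:01:01|DRB1*001:01	53	3.30	47	6	8	NA	NA
21	88*508:01|12*001:01:03|DRB1*012:01	50	3.11	42	8	3	NA	NA
7	88*012:01|12*001:01:01|DRB1*015:01	48	2.99	42	6	9	NA	NA
23	88*013:02|12*003:01|DRB1*009:01	46	2.86	33	13	2	Miniature Schnauzer	95.7
116	88*006:01|12*001:01:01|DRB1*056:01	41	2.55	31	10	1	Shiba	95.1
73	88*051:01|12*001:01:01|DRB1*012:01	40	2.49	33	7	2	Golden Retriever	85.0
6	88*502:01|12*001:01:01|DRB1*001:02	38	2.37	28	10	1	Beagle	94.7
63	88*004:02|12*001:01:01|DRB1*015:01	34	2.12	28	6	14	NA	NA
18	88*005:01|12*002:04|DRB1*020:01	32	1.99	28	4	9	NA	NA
17	88*501:01|12*001:01:01|DRB1*006:01	31	1.93	27	4	8	NA	NA
2	88*006:01|12*001:01:01|DRB1*006:01	30	1.87	24	6	8	American Cocker Spaniel	70.0
51	88*034:01|12*002:03|DRB1*023:01	29	1.81	23	6	5	Shetland Sheepdog	75.9
91	88*001:03|12*001:01:01|DRB1*046:01	26	1.62	18	8	1	Papillon	96.2
46	88*014:01:02|12*001:05|DRB1*025:01	25	1.56	19	6	4	Shih Tzu	72.0
71	88*002:01|12*001:01:01|DRB1*011:01	23	1.43	22	1	3	NA	NA
52	88*006:01|12*001:01:01|DRB1*002:03	23	1.43	21	2	2	Dachshund	78.3
66	88*006:01|12*001:01:01|DRB1*001:01	22	1.37	22	0	6	NA	NA
10	88*508:01|12*001:01:03|DRB1*002:01	21	1.31	21	0	7	NA	NA
22	88*511:01|12*001:03|DRB1*015:02	21	1.31	19	2	3	Labrador Retriever	90.5
99	88*035:01|12*nov18|DRB1*006:01	20	1.25	15	5	2	Shih Tzu	85.0
69	88*054:01|12*002:02|DRB1*012:01	20	1.25	17	3	2	Welsh Corgi	85.0
37	88*006:01|12*001:01:01|DRB1*015:01	18	1.12	17	1	3	Toy Poodle	77.8
48	88*028:05|88L*029:01|DRB1*015:02	18	1.12	18	0	6	NA	NA
33	88*501:01|12*001:01:01|DRB1*012:01	16	1.00	16	0	5	NA	NA
117	88*511:01|12*001:03|DRB1*092:01:1	16	1.00	15	1	1	Shiba	87.5
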