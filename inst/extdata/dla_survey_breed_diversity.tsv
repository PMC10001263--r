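breed	n_assigned	n_unassigned	n_haplotypes	n_homozygous	ho	he	hwe	fis	hr
Shetland Sheepdog	35	0	3	24	0.314	0.450	-	0.315	2.13
American Cocker Spaniel	20	0	5	9	0.550	0.580	p<0.05	0.077	2.94
Miniature Schnauzer	32	1	9	12	0.625	0.510	-	-0.21	3.62
Cavalier King Charles Spaniel	18	0	6	5	0.722	0.716	p<0.001	0.020	3.79
Shiba	37	0	11	14	0.622	0.658	p<0.001	0.069	3.95
Golden Retriever	39	2	11	11	0.718	0.713	p<0.001	0.006	4.26
Papillon	24	0	9	10	0.583	0.687	p<0.05	0.171	4.60
Shih Tzu	28	0	12	10	0.643	0.762	p<0.001	0.209	4.64
Miniature Pinscher	12	0	6	2	0.833	0.771	-	-0.038	4.64
Bernese Mountain Dog	11	0	7	3	0.727	0.698	-	0.006	4.79
French Bulldog	38	0	10	12	0.684	0.751	-	0.102	4.87
Husky	12	0	8	5	0.583	0.733	-	0.245	5.06
Beagle	37	2	13	11	0.703	0.730	p<0.05	0.051	5.10
Bulldog	10	0	7	2	0.800	0.790	-	0.040	5.20
Labrador Retriever	38	1	15	7	0.821	0.807	p<0.001	0.003	5.50
Welsh Corgi	31	2	9	5	0.848	0.837	-	0.015	5.62
Pomeranian	29	0	17	6	0.793	0.757	-	-0.03	5.64
Yorkshire Terrier	41	0	13	3	0.927	0.836	-	-0.096	5.85
Pug	21	0	11	4	0.810	0.840	-	0.061	5.87
Maltese	26	0	13	5	0.808	0.847	-	0.066	6.02
Miniature Dachshund	49	0	15	5	0.898	0.874	-	-0.018	6.40
Border Collie	19	0	12	4	0.789	0.871	-	0.121	6.52
Chihuahua	39	0	20	2	0.949	0.917	-	-0.022	7.44
Toy Poodle	44	0	27	4	0.909	0.927	-	0.031	7.79
Mongrel	27	0	34	1	0.963	0.962	-	0.018	9.16
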