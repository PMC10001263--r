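breed	hp_id	haplotype	carriers	n_total	pct
Miniature Schnauzer	23	88*013:02|12*003:01|DRB1*009:01	32	33	97.0
Shetland Sheepdog	20	88*003:02|88L*017:01|DRB1*002:01	29	35	82.9
American Cocker Spaniel	31	88*003:02|88L*017:01|DRB1*009:01	16	20	80.0
Shiba	116	88*006:01|12*001:01:01|DRB1*056:01	29	37	78.4
Pomeranian	12	88*004:02|12*001:01:01|DRB1*006:01	22	29	75.9
Bernese Mountain Dog	17	88*501:01|12*001:01:01|DRB1*006:01	8	11	72.7
Papillon	91	88*001:03|12*001:01:01|DRB1*046:01	17	24	70.8
Beagle	6	88*502:01|12*001:01:01|DRB1*001:02	26	39	66.7
French Bulldog	25	88*028:01|88L*029:01|DRB1*015:02	25	38	65.8
Golden Retriever	33	88*501:01|12*001:01:01|DRB1*012:01	26	41	63.4
Cavalier King Charles Spaniel	71	88*002:01|12*001:01:01|DRB1*011:01	11	18	61.1
Yorkshire Terrier	12	88*004:02|12*001:01:01|DRB1*006:01	24	41	58.5
Husky	77	88*060:02|12*001:01:04|DRB1*040:01	7	12	58.3
Labrador Retriever	21	88*508:01|12*001:01:03|DRB1*012:01	21	39	53.8
Bulldog	25	88*028:01|88L*029:01|DRB1*015:02	5	10	50.0
Miniature Pinscher	63	88*004:02|12*001:01:01|DRB1*015:01	6	12	50.0
Shih Tzu	46	88*014:01:02|12*001:05|DRB1*025:01	14	28	50.0
Welsh Corgi	69	88*054:01|12*002:02|DRB1*012:01	15	33	45.5
Maltese	7	88*012:01|12*001:01:01|DRB1*015:01	11	26	42.3
Miniature Dachshund	8	88*501:01|12*001:01:01|DRB1*001:01	20	49	40.8
Pug	110	88*058:01|88L*024:03|DRB1*010:011	8	21	38.1
Border Collie	24	88*028:03|88L*029:01|DRB1*015:02	6	19	31.6
Toy Poodle	37	88*006:01|12*001:01:01|DRB1*015:01	13	44	29.5
Chihuahua	30	88*508:01|12*001:01:03|DRB1*015:01	10	39	25.6
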