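gene	disease	moi	versions	category	severity	likelihood	likelihood_ev	effectiveness	effectiveness_ev	nature	curated	hpo_terms
ABCA4	Age-related macular degeneration 2	AD		eye	2	3	B	3	B	3	TRUE	HP:0000608
ABCA4	Stargardt disease 1	AR		eye	2	3	A	3	B	2	TRUE	HP:0007754
BEST1	Vitelliform macular dystrophy 4	AD		eye	2	3	B	2	C	3	TRUE	HP:0000478
ABCG8	Sitosterolemia 1	AR		metabolic	3	2	B	3	A	3	TRUE	HP:0001939
AGXT	Primary hyperoxaluria 1	AR		metabolic	3	3	A	2	B	2	TRUE	HP:0001939
COQ8B	Nephrotic syndrome 9	AR		urinary	3	2	B	2	B	3	TRUE	HP:0000079
SLC5A2	Renal glucosuria	AD		urinary	1	3	B	3	A	3	TRUE	HP:0000079
SLC34A1	Fanconi renotubular syndrome 2	AR		other	2	3	C	2	B	3	TRUE	HP:0025142
MFAP5	Familial thoracic aortic aneurysm 9	AD		CVD	3	2	C	3	B	2	TRUE	HP:0001626
DNAH5	Primary ciliary dyskinesia 3	AR		respiratory	2	3	A	2	B	3	TRUE	HP:0002086
IYD	Thyroid dyshormonogenesis 5	AR		endocrine	2	3	B	3	A	3	TRUE	HP:0000818
VWF	von Willebrand disease 1	AD		hematologic	2	3	A	3	A	3	TRUE	HP:0001871
COL7A1	Epidermolysis bullosa dystrophica	AR		dermatologic	3	3	A	2	B	2	TRUE	HP:0008066;HP:0000951
PHOX2B	Congenital central hypoventilation syndrome 2	AD		other	3	3	B	2	B	2	TRUE	HP:0025142
THBD	Atypical hemolytic uremic syndrome 6	AD		hematologic	3	2	B	3	B	2	TRUE	HP:0001871
CFTR	Cystic fibrosis	AR		respiratory	3	3	A	3	A	2	TRUE	HP:0002205;HP:0002086
ITGB4	Junctional epidermolysis bullosa 5A	AR		dermatologic	3	2	B	2	B	3	TRUE	HP:0000951
MEFV	Familial Mediterranean fever	AR		other	2	3	A	3	A	3	TRUE	HP:0025142
SLC7A9	Cystinuria	AR		urinary	2	3	A	3	A	2	TRUE	HP:0000079
SYNG01	Synthetic placeholder disease 1	AD		CVD	3	2	N	3	N	3	TRUE	HP:0001626
SYNG02	Synthetic placeholder disease 2	AR		cancer	3	2	N	3	N	2	TRUE	HP:0002664
SYNG03	Synthetic placeholder disease 3	AR		metabolic	3	2	N	3	N	3	TRUE	HP:0001939
SYNG04	Synthetic placeholder disease 4	AD		eye	3	2	N	3	N	2	TRUE	HP:0000478
SYNG05	Synthetic placeholder disease 5	XL		urinary	3	2	N	3	N	3	TRUE	HP:0000079
SYNG06	Synthetic placeholder disease 6	AD		respiratory	3	2	N	3	N	2	TRUE	HP:0002086
SYNG07	Synthetic placeholder disease 7	AR		endocrine	3	2	N	3	N	3	TRUE	HP:0000818
SYNG08	Synthetic placeholder disease 8	AR		hematologic	3	2	N	3	N	2	TRUE	HP:0001871
SYNG09	Synthetic placeholder disease 9	AD		dermatologic	3	2	N	3	N	3	TRUE	HP:0000951
SYNG10	Synthetic placeholder disease 10	XL		other	3	2	N	3	N	2	TRUE	HP:0025142
SYNG11	Synthetic placeholder disease 11	AD		CVD	3	2	N	3	N	3	TRUE	HP:0001626
SYNG12	Synthetic placeholder disease 12	AR		cancer	3	2	N	3	N	2	TRUE	HP:0002664
SYNG13	Synthetic placeholder disease 13	AR		metabolic	3	2	N	3	N	3	TRUE	HP:0001939
SYNG14	Synthetic placeholder disease 14	AD		eye	3	2	N	3	N	2	TRUE	HP:0000478
SYNG15	Synthetic placeholder disease 15	XL		urinary	3	2	N	3	N	3	TRUE	HP:0000079
SYNG16	Synthetic placeholder disease 16	AD		respiratory	3	2	N	3	N	2	TRUE	HP:0002086
SYNG17	Synthetic placeholder disease 17	AR		endocrine	3	2	N	3	N	3	TRUE	HP:0000818
SYNG18	Synthetic placeholder disease 18	AR		hematologic	3	2	N	3	N	2	TRUE	HP:0001871
SYNG19	Synthetic placeholder disease 19	AD		dermatologic	3	2	N	3	N	3	TRUE	HP:0000951
SYNG20	Synthetic placeholder disease 20	XL		other	3	2	N	3	N	2	TRUE	HP:0025142
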