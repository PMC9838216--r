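gene	disease	moi	versions	category	severity	likelihood	likelihood_ev	effectiveness	effectiveness_ev	nature	curated	hpo_terms
ACTA2	Familial thoracic aortic aneurysm 6	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
ACTC1	Dilated cardiomyopathy 1R	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
APC	Familial adenomatous polyposis	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
APOB	Familial hypercholesterolemia 2	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
BRCA1	Hereditary breast and ovarian cancer	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
BRCA2	Hereditary breast and ovarian cancer	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
CACNA1S	Malignant hyperthermia 5	AD	v1.0;v2.0;v3.0;v3.1	other								HP:0025142
COL3A1	Vascular Ehlers-Danlos syndrome	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
DSC2	Arrhythmogenic right ventricular cardiomyopathy 11	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
DSG2	Arrhythmogenic right ventricular cardiomyopathy 10	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
DSP	Arrhythmogenic right ventricular cardiomyopathy 8	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
FBN1	Marfan syndrome	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001166;HP:0001626
GLA	Fabry disease	XL	v1.0;v2.0;v3.0;v3.1	metabolic								HP:0001939
KCNH2	Long QT syndrome 2	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
KCNQ1	Long QT syndrome 1	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
LDLR	Familial hypercholesterolemia 1	SD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0003124;HP:0001626
LMNA	Dilated cardiomyopathy 1A	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
MEN1	Multiple endocrine neoplasia 1	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
MLH1	Lynch syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
MSH2	Lynch syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
MSH6	Lynch syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
MUTYH	MUTYH-related familial adenomatous polyposis	AR	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
MYBPC3	Hypertrophic cardiomyopathy 4	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001639;HP:0001626
MYH11	Familial thoracic aortic aneurysm 4	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
MYH7	Hypertrophic cardiomyopathy 1	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001639;HP:0001626
MYL2	Hypertrophic cardiomyopathy 10	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
MYL3	Hypertrophic cardiomyopathy 8	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
MYLK	Familial thoracic aortic aneurysm 7	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
NF2	Neurofibromatosis 2	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
PCSK9	Familial hypercholesterolemia 3	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
PKP2	Arrhythmogenic right ventricular cardiomyopathy 9	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
PMS2	Lynch syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
PRKAG2	Wolff-Parkinson-White with cardiomyopathy	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
PTEN	PTEN hamartoma tumor syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
RB1	Retinoblastoma	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0009919;HP:0002664
RET	Multiple endocrine neoplasia 2	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
RYR1	Malignant hyperthermia 1	AD	v1.0;v2.0;v3.0;v3.1	other								HP:0025142
RYR2	Catecholaminergic polymorphic ventricular tachycardia 1	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
SCN5A	Brugada syndrome 1	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
SDHAF2	Hereditary paraganglioma-pheochromocytoma	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
SDHB	Hereditary paraganglioma-pheochromocytoma	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
SDHC	Hereditary paraganglioma-pheochromocytoma	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
SDHD	Hereditary paraganglioma-pheochromocytoma	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
SMAD3	Loeys-Dietz syndrome 3	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
STK11	Peutz-Jeghers syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0004390;HP:0002664
TGFBR1	Loeys-Dietz syndrome 1	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
TGFBR2	Loeys-Dietz syndrome 2	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
TMEM43	Arrhythmogenic right ventricular dysplasia 5	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
TNNI3	Hypertrophic cardiomyopathy 7	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001639;HP:0001626
TNNT2	Dilated cardiomyopathy 1D / hypertrophic cardiomyopathy 2	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001644;HP:0001626
TP53	Li-Fraumeni syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
TPM1	Hypertrophic cardiomyopathy 3	AD	v1.0;v2.0;v3.0;v3.1	CVD								HP:0001626
TSC1	Tuberous sclerosis 1	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
TSC2	Tuberous sclerosis 2	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
VHL	Von Hippel-Lindau syndrome	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
WT1	Wilms tumor 1	AD	v1.0;v2.0;v3.0;v3.1	cancer								HP:0002664
ATP7B	Wilson disease	AR	v2.0;v3.0;v3.1	metabolic								HP:0001392;HP:0001939
BMPR1A	Juvenile polyposis syndrome	AD	v2.0;v3.0;v3.1	cancer								HP:0002664
OTC	Ornithine transcarbamylase deficiency	XL	v2.0;v3.0;v3.1	metabolic								HP:0001939
SMAD4	Juvenile polyposis syndrome	AD	v2.0;v3.0;v3.1	cancer								HP:0002664
PALB2	Hereditary breast cancer	AD	v2.0;v3.0;v3.1	cancer								HP:0002664
ACVRL1	Hereditary hemorrhagic telangiectasia 2	AD	v3.0;v3.1	CVD								HP:0001626
BTD	Biotinidase deficiency	AR	v3.0;v3.1	metabolic								HP:0001250;HP:0001939
CASQ2	Catecholaminergic polymorphic ventricular tachycardia 2	AR	v3.0;v3.1	CVD								HP:0001626
ENG	Hereditary hemorrhagic telangiectasia 1	AD	v3.0;v3.1	CVD								HP:0001626
FLNC	Dilated cardiomyopathy 1JJ	AD	v3.0;v3.1	CVD								HP:0001626
GAA	Pompe disease	AR	v3.0;v3.1	metabolic								HP:0003198;HP:0001939
HFE	Hereditary hemochromatosis 1	AR	v3.0;v3.1	metabolic								HP:0001939
HNF1A	Maturity-onset diabetes of the young 3	AD	v3.0;v3.1	endocrine								HP:0000818
MAX	Hereditary pheochromocytoma	AD	v3.0;v3.1	cancer								HP:0002664
RPE65	RPE65-related retinopathy	AR	v3.0;v3.1	eye								HP:0000478
TMEM127	Hereditary pheochromocytoma	AD	v3.0;v3.1	cancer								HP:0002664
TRDN	Catecholaminergic polymorphic ventricular tachycardia 5	AR	v3.0;v3.1	CVD								HP:0001626
TTN	Dilated cardiomyopathy 1G	AD	v3.0;v3.1	CVD								HP:0001644;HP:0001626
TTR	Hereditary transthyretin amyloidosis	AD	v3.1	CVD								HP:0001626
BAG3	Dilated cardiomyopathy 1HH	AD	v3.1	CVD								HP:0001626
DES	Desmin-related cardiomyopathy	AD	v3.1	CVD								HP:0001626
RBM20	Dilated cardiomyopathy 1DD	AD	v3.1	CVD								HP:0001626
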