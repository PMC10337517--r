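variant	cui	snomed_code	preferred_term	semantic_type_code
diabetes	C0011854	73211009	Diabetes mellitus	T047
diabetes mellitus	C0011854	73211009	Diabetes mellitus	T047
type 2 diabetes	C0011860	44054006	Type 2 diabetes mellitus	T047
typediabetes	C0011854	73211009	Diabetes mellitus	T047
asthma	C0004096	195967001	Asthma	T047
allergic asthma	C0155877	389145006	Allergic asthma	T047
hypertension	C0020538	38341003	Hypertensive disease	T047
high blood pressure	C0020538	38341003	Hypertensive disease	T047
colon cancer	C0007102	363406005	Malignant tumor of colon	T191
cancer	C0006826	363346000	Malignant neoplastic disease	T191
breast cancer	C0006142	254837009	Malignant tumor of breast	T191
stroke	C0038454	230690007	Cerebrovascular accident	T047
heart attack	C0027051	22298006	Myocardial infarction	T047
myocardial infarction	C0027051	22298006	Myocardial infarction	T047
depression	C0011570	35489007	Mental depression	T048
anxiety	C0003467		Anxiety	T033
seizure	C0036572	91175000	Seizure	T184
migraine	C0149931	37796009	Migraine disorders	T047
smoking	C0037369		Smoking	T033
obesity	C0028754	414916001	Obesity	T047
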