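trigger	category	side	degree	spouse
mother	Mother		1	0
mom	Mother		1	0
father	Father		1	0
dad	Father		1	0
parent	Parent		1	0
parents	Parent		1	0
brother	Brother		1	0
brothers	Brother		1	0
sister	Sister		1	0
sisters	Sister		1	0
sibling	Sibling		1	0
siblings	Sibling		1	0
son	Son		1	0
sons	Son		1	0
daughter	Daughter		1	0
daughters	Daughter		1	0
child	Child		1	0
children	Child		1	0
grandmother	Grandmother		2	0
grandma	Grandmother		2	0
grandfather	Grandfather		2	0
grandpa	Grandfather		2	0
grandparent	Grandparent		2	0
grandparents	Grandparent		2	0
aunt	Aunt		2	0
aunts	Aunt		2	0
uncle	Uncle		2	0
uncles	Uncle		2	0
half brother	Sibling		2	0
half-brother	Sibling		2	0
half sister	Sibling		2	0
half-sister	Sibling		2	0
cousin	Cousin		3	0
cousins	Cousin		3	0
great grandmother	Grandmother		3	0
great-grandmother	Grandmother		3	0
great grandfather	Grandfather		3	0
great-grandfather	Grandfather		3	0
great grandparents	Grandparent		3	0
niece	EXT		2	0
nephew	EXT		2	0
nieces	EXT		2	0
nephews	EXT		2	0
husband			NA	1
wife			NA	1
spouse			NA	1
mother-in-law			NA	1
father-in-law			NA	1
sister-in-law			NA	1
brother-in-law			NA	1
son-in-law			NA	1
daughter-in-law			NA	1
in-laws			NA	1
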