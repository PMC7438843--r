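feature	rank_knn	rank_rf	rank_svm
Parvimonas	3	4	4
Lactobacillus iners	6	1	13
Fastidiosipila	5	12	11
Negativicoccus	1	2	27
Lactobacillus crispatus	10	20	7
Dialister	16	5	19
Sneathia sanguinegens	11	7	22
Gardnerella vaginalis	8	8	26
Prevotella corporis	18	15	9
Corynebacterium	17	16	16
Sneathia amnii	4	9	42
Chryseobacterium	33	10	14
Acinetobacter	7	6	45
Escherichia shigella	15	45	2
Gemella	40	3	20
Prevotella timonensis	30	28	5
Circumcised	9	27	32
Peptostreptococcus	2	18	49
Ezakiella	21	11	43
Alloprevotella	19	23	36
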