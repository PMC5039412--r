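rank	drug	disease	score	curated_mark
1	imipramine	Bipolar Disorder	8.800	M&T
2	amitriptyline	Bipolar Disorder	8.510	T
3	imipramine	Depressive Disorder, Major	7.960	M&T
4	amitriptyline	Depressive Disorder, Major	7.860	M&T
5	desipramine	Bipolar Disorder	7.380	M&T
6	amitriptyline	Depressive Disorder	6.930	M&T
7	imipramine	Depressive Disorder	6.670	T
8	amitriptyline	Mood Disorders	6.640	M&T
9	desipramine	Depressive Disorder, Major	6.620	T
10	nortriptyline	Bipolar Disorder	6.590	M
11	imipramine	Mood Disorders	6.470	T
12	amitriptyline	Personality Disorders	6.210	T
13	nortriptyline	Depressive Disorder, Major	6.210	M&T
14	amitriptyline	Anxiety Disorders	5.880	T
15	amitriptyline	Sleep Disorders, Circadian Rhythm	5.820	none
16	amitriptyline	Dyssomnias	5.770	M&T
17	desipramine	Depressive Disorder	5.490	M&T
18	desipramine	Mood Disorders	5.370	M
19	amitriptyline	Schizophrenia	5.320	T
20	imipramine	Depression, Postpartum	5.230	none
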