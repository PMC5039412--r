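rank	drug	disease	score	curated_mark
1	chlorpromazine	Psychotic Disorders	5.360	T
2	chlorpromazine	Schizophrenia	5.190	T
3	chlorpromazine	Psychoses, Substance-Induced	5.190	M&T
4	perphenazine	Schizophrenia	5.150	T
5	Thorazine	Bipolar Disorder	5.070	M&T
6	thiothixene	Psychotic Disorders	4.910	M&T
7	trifluoperazine	Psychotic Disorders	4.720	T
8	trifluoperazine	Psychoses, Substance-Induced	4.580	M
9	trifluoperazine	Schizophrenia	4.570	T
10	thioridazine	Psychoses, Substance-Induced	4.560	none
11	trifluoperazine	Bipolar Disorder	4.540	T
12	fluphenazine	Psychotic Disorders	4.420	T
13	fluphenazine	Schizophrenia	4.240	T
14	fluphenazine	Bipolar Disorder	4.160	T
15	fluphenazine	Psychoses, Substance-Induced	4.100	M
16	thorazine	Lewy Body Disease	4.070	inferred
17	perphenazine	Bipolar Disorder	3.890	T
18	prochlorperazine	Bipolar Disorder	3.810	none
19	perphenazine	Psychotic Disorders	3.780	T
20	chlorpromazine	Alcohol Withdrawal Delirium	3.680	none
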