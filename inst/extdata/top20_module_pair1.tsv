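rank	drug	disease	score	curated_mark
1	trifluoperazine	Basal Ganglia Diseases	7.360	M
2	thorazine	Basal Ganglia Diseases	7.150	M&T
3	perphenazine	Basal Ganglia Diseases	7.010	M
4	trifluoperazine	Movement Disorders	6.920	M
5	trifluoperazine	Dyskinesia, Drug-Induced	6.810	M
6	trifluoperazine	Parkinson Disease, Secondary	6.730	M
7	Thorazine	Movement Disorders	6.710	M&T
8	Thorazine	Dyskinesia, Drug-Induced	6.620	M&T
9	prochlorperazine	Tremor	6.590	none
10	perphenazine	Movement Disorders	6.560	M&T
11	Thorazine	Parkinson Disease, Secondary	6.540	M
12	thioridazine	Basal Ganglia Diseases	6.440	M
13	perphenazine	Dyskinesia, Drug-Induced	6.430	M
14	perphenazine	Parkinson Disease, Secondary	6.360	M
15	prochlorperazine	Parkinsonian Disorders	6.340	M
16	perphenazine	Tremor	6.220	M
17	trifluoperazine	Tremor	6.220	M
18	Thorazine	Tremor	6.180	M
19	fluphenazine	Parkinsonian Disorders	6.060	inferred
20	prochlorperazine	Basal Ganglia Diseases	6.030	M
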