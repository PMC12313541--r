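exposure	outcome	mediator	c_est	c_lo	c_hi	a_est	a_lo	a_hi	b_est	b_lo	b_hi	c_adj_est	c_adj_lo	c_adj_hi	b_adj_est	b_adj_lo	b_adj_hi
Alcohol intake frequency	IBS	Depression (broad)	0.162	0.090	0.234	0.033	0.015	0.050	0.42	0.321	0.519	0.082	0.019	0.144	1.238	0.911	1.565
Alcohol intake frequency	IBS	MDD	0.162	0.090	0.234	0.111	0.057	0.165	0.293	0.243	0.343	-0.009	-0.105	0.087	0.668	0.403	0.933
Alcohol intake frequency	IBS	ADHD	0.162	0.090	0.234	0.318	0.212	0.424	0.062	0.034	0.089	0.141	0.033	0.249	0.084	-0.039	0.207
Alcohol intake frequency	IBS	PTSD	0.162	0.090	0.234	0.385	0.226	0.544	0.002	-0.041	0.045	0.114	0.021	0.207	-0.017	-0.124	0.091
Alcohol intake frequency	IBS	PPD	0.162	0.090	0.234	0.198	0.054	0.342	-0.008	-0.028	0.014	0.113	0.020	0.206	-0.01	-0.132	0.111
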