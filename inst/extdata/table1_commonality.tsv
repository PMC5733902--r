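subset	order	coef_area85	coef_area130	coef_area131
E	1	0.008	0.001	0.002
T	1	0.050	0.070	0.059
Pc	1	0.004	0.008	0.008
Pr	1	0.085	0.047	0.046
E,T	2	0.136	0.117	0.115
E,Pc	2	-0.003	-0.001	-0.001
T,Pc	2	0.001	0.007	0.010
E,Pr	2	-0.002	0.031	0.020
T,Pr	2	-0.013	0.018	0.014
Pc,Pr	2	0.024	0.008	0.011
E,T,Pc	3	0.014	-0.005	-0.001
E,T,Pr	3	-0.023	-0.069	-0.047
E,Pc,Pr	3	0.003	0.026	0.030
T,Pc,Pr	3	-0.009	0.006	0.010
E,T,Pc,Pr	4	-0.034	-0.049	-0.068
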