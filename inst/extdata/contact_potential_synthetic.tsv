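aa	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-0.504	0.945	0.715	0.715	-0.665	0.715	0.715	0.002	0.646	-1.125	-0.964	0.807	-0.527	-0.734	0.278	0.094	0.071	0.117	0.209	-1.056
R	0.945	-1.575	-1.175	-1.175	1.225	-1.175	-1.175	0.065	-1.055	2.025	1.745	-1.335	0.985	1.345	-0.415	-0.095	-0.055	-0.135	-0.295	1.905
N	0.715	-1.175	-0.875	-0.875	0.925	-0.875	-0.875	0.055	-0.785	1.525	1.315	-0.995	0.745	1.015	-0.305	-0.065	-0.035	-0.095	-0.215	1.435
D	0.715	-1.175	-0.875	-0.875	0.925	-0.875	-0.875	0.055	-0.785	1.525	1.315	-0.995	0.745	1.015	-0.305	-0.065	-0.035	-0.095	-0.215	1.435
C	-0.665	1.225	0.925	0.925	-0.875	0.925	0.925	-0.005	0.835	-1.475	-1.265	1.045	-0.695	-0.965	0.355	0.115	0.085	0.145	0.265	-1.385
Q	0.715	-1.175	-0.875	-0.875	0.925	-0.875	-0.875	0.055	-0.785	1.525	1.315	-0.995	0.745	1.015	-0.305	-0.065	-0.035	-0.095	-0.215	1.435
E	0.715	-1.175	-0.875	-0.875	0.925	-0.875	-0.875	0.055	-0.785	1.525	1.315	-0.995	0.745	1.015	-0.305	-0.065	-0.035	-0.095	-0.215	1.435
G	0.002	0.065	0.055	0.055	-0.005	0.055	0.055	0.024	0.052	-0.025	-0.018	0.059	0.001	-0.008	0.036	0.028	0.027	0.029	0.033	-0.022
H	0.646	-1.055	-0.785	-0.785	0.835	-0.785	-0.785	0.052	-0.704	1.375	1.186	-0.893	0.673	0.916	-0.272	-0.056	-0.029	-0.083	-0.191	1.294
I	-1.125	2.025	1.525	1.525	-1.475	1.525	1.525	-0.025	1.375	-2.475	-2.125	1.725	-1.175	-1.625	0.575	0.175	0.125	0.225	0.425	-2.325
L	-0.964	1.745	1.315	1.315	-1.265	1.315	1.315	-0.018	1.186	-2.125	-1.824	1.487	-1.007	-1.394	0.498	0.154	0.111	0.197	0.369	-1.996
K	0.807	-1.335	-0.995	-0.995	1.045	-0.995	-0.995	0.059	-0.893	1.725	1.487	-1.131	0.841	1.147	-0.349	-0.077	-0.043	-0.111	-0.247	1.623
M	-0.527	0.985	0.745	0.745	-0.695	0.745	0.745	0.001	0.673	-1.175	-1.007	0.841	-0.551	-0.767	0.289	0.097	0.073	0.121	0.217	-1.103
F	-0.734	1.345	1.015	1.015	-0.965	1.015	1.015	-0.008	0.916	-1.625	-1.394	1.147	-0.767	-1.064	0.388	0.124	0.091	0.157	0.289	-1.526
P	0.278	-0.415	-0.305	-0.305	0.355	-0.305	-0.305	0.036	-0.272	0.575	0.498	-0.349	0.289	0.388	-0.096	-0.008	0.003	-0.019	-0.063	0.542
S	0.094	-0.095	-0.065	-0.065	0.115	-0.065	-0.065	0.028	-0.056	0.175	0.154	-0.077	0.097	0.124	-0.008	0.016	0.019	0.013	0.001	0.166
T	0.071	-0.055	-0.035	-0.035	0.085	-0.035	-0.035	0.027	-0.029	0.125	0.111	-0.043	0.073	0.091	0.003	0.019	0.021	0.017	0.009	0.119
W	0.117	-0.135	-0.095	-0.095	0.145	-0.095	-0.095	0.029	-0.083	0.225	0.197	-0.111	0.121	0.157	-0.019	0.013	0.017	0.009	-0.007	0.213
Y	0.209	-0.295	-0.215	-0.215	0.265	-0.215	-0.215	0.033	-0.191	0.425	0.369	-0.247	0.217	0.289	-0.063	0.001	0.009	-0.007	-0.039	0.401
V	-1.056	1.905	1.435	1.435	-1.385	1.435	1.435	-0.022	1.294	-2.325	-1.996	1.623	-1.103	-1.526	0.542	0.166	0.119	0.213	0.401	-2.184
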