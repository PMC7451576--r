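response	model_id	Manta	Lumpy	GRIDSS	SvABA	Delly
sensitivity	1	0.041	0.034	0.051	0.052	0.021
sensitivity	2	0.041	0.034	0.051	0.053	0.021
sensitivity	3	0.042	0.034	0.051	0.052	0.021
sensitivity	4	0.042	0.034	0.051	0.053	0.021
sensitivity	5	0.042	0.034	0.051	0.053	0.021
sensitivity	6	0.042	0.036	0.051	0.058	0.021
sensitivity	7	0.068	0.061	0.092	0.091	0.026
sensitivity	8	0.136	0.094	0.144	0.148	0.167
precision	1	0.012	0.012	0.007	0.029	0.061
precision	2	0.012	0.012	0.007	0.029	0.061
precision	3	0.012	0.013	0.007	0.029	0.156
precision	4	0.013	0.013	0.007	0.029	0.156
precision	5	0.017	0.013	0.007	0.029	0.156
precision	6	0.019	0.017	0.007	0.032	0.156
precision	7	0.018	0.015	0.012	0.046	0.151
precision	8	0.024	0.020	0.013	0.055	0.148
f1	1	0.039	0.032	0.048	0.057	0.019
f1	2	0.039	0.032	0.048	0.058	0.019
f1	3	0.040	0.032	0.048	0.057	0.019
f1	4	0.040	0.032	0.048	0.058	0.019
f1	5	0.040	0.032	0.048	0.060	0.019
f1	6	0.040	0.034	0.048	0.065	0.020
f1	7	0.066	0.060	0.091	0.101	0.021
f1	8	0.132	0.088	0.143	0.163	0.146
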