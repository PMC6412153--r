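symbol	score
G00006	0.29
G00014	0.1
G00015	0.31
G00025	0.81
G00035	0.72
G00039	0.99
G00040	0.34
G00049	0.69
G00050	0.66
G00051	0.01
G00056	0.12
G00059	0.02
G00060	0.81
G00063	0.45
G00068	0.98
G00071	0.17
G00073	0.92
G00077	0.94
G00080	0.01
G00082	0.11
G00083	0.18
G00087	0.65
G00093	0.19
G00100	0.51
G00105	0.01
G00107	0.16
G00116	0.53
G00131	0.5
G00132	0.73
G00134	0.43
G00136	0.77
G00137	0.66
G00147	0.47
G00149	0.34
G00151	0.97
G00154	0.32
G00161	0.64
G00172	0.57
G00180	1
G00189	0.97
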