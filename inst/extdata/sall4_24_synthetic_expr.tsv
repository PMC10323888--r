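gene_id	SYN01	SYN02	SYN03	SYN04	SYN05	SYN06	SYN07	SYN08
ANTXR1	6.604	6.008	7.052	8.703	6.738	8.149	5.503	7.307
CASC15	7.62	7.232	6.67	7.496	7.854	7.085	7.894	7.605
COL1A1	6.915	7.793	7.426	8.291	6.419	9.387	7.258	6.804
COL5A2	7.026	5.69	6.444	5.586	7.928	6.347	8.578	6.616
COL8A1	5.672	8.755	8.55	7.896	8.181	7.372	7.592	6.598
COL11A1	5.521	5.765	8.83	6.846	4.907	7.738	9.063	6.221
DCBLD1	8.731	8.17	5.663	5.851	7.106	5.665	8.432	6.935
DLG4	8.544	8.103	6.019	6.272	4.811	7.581	7.487	6.918
ITGA11	8.157	4.984	7.622	6.676	7.677	5.825	7.985	8.18
KANK4	6.52	7.078	6.81	7.941	5.923	7.118	5.456	7.47
LRRC15	6.184	5.284	6.645	6.356	6.138	8.881	6.586	7.698
MEIS3	7.11	8.235	7.954	7.837	6.815	5.787	6.277	7.424
MMP11	6.109	7.435	6.401	6.913	6.51	7.384	6.817	5.869
MMP14	7.141	7.962	5.86	6.498	5.651	6.697	7.616	7.145
NOTCH3	7.225	7.815	7.309	6.4	6.902	7.636	7.108	7.749
NOX4	6.743	6.711	8.068	5.359	6.053	7.073	6.157	7.142
NUAK1	8.712	5.913	8.557	6.826	8.049	6.854	8.163	7.882
PPEF1	8.528	7.066	7.573	6.774	6.667	5.448	6.509	6.681
PPFIBP1	8.77	6.967	7.18	8.119	9.232	5.876	8.141	7.119
PTK7	6.458	7.585	8.167	7.842	6.953	7.371	8.052	7.254
SERPINH1	5.301	5.74	5.95	6.227	8.22	7.847	7.887	8.236
SOX11	7.705	6.966	6.539	6.384	7.202	7.022	5.04	7.68
SPOCD1	6.153	7.893	6.417	7.403	7.984	7.311	7.489	7.415
UNC5B	8.087	7.994	6.73	6.609	6.633	7.277	7.995	7.614
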