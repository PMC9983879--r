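FID	IID	M	Y
id0001	id0001	-0.8318	-1.949
id0002	id0002	0.0026	0.9153
id0003	id0003	-0.0306	0.5076
id0004	id0004	-1.188	0.2972
id0005	id0005	-1.6792	-0.7463
id0006	id0006	0.4902	0.0767
id0007	id0007	1.0521	0.2283
id0008	id0008	-1.8527	-2.633
id0009	id0009	2.6628	3.1851
id0010	id0010	-1.6667	-0.9073
id0011	id0011	0.9358	0.7339
id0012	id0012	0.1624	1.6474
id0013	id0013	0.0701	1.7666
id0014	id0014	-2.317	-2.6868
id0015	id0015	-0.2783	-1.7319
id0016	id0016	-0.2299	0.86
id0017	id0017	0.3696	1.4361
id0018	id0018	0.7711	-0.8641
id0019	id0019	-1.8154	-4.3
id0020	id0020	1.8332	1.4023
id0021	id0021	-1.0671	-1.303
id0022	id0022	2.4764	4.7113
id0023	id0023	0.3138	0.8728
id0024	id0024	-1.2692	-5.1429
id0025	id0025	-2.6565	-2.0694
id0026	id0026	-1.0762	-1.7993
id0027	id0027	-1.0049	-1.3105
id0028	id0028	-0.3239	-1.2461
id0029	id0029	-0.5311	1.0928
id0030	id0030	0.3061	0.3427
id0031	id0031	-4.6345	-5.7668
id0032	id0032	0.5639	-0.8157
id0033	id0033	-0.4965	-0.7723
id0034	id0034	2.2219	0.947
id0035	id0035	2.2404	0.6646
id0036	id0036	-2.5626	-3.133
id0037	id0037	3.0945	4.5016
id0038	id0038	-0.8139	-1.8018
id0039	id0039	0.0559	-2.2929
id0040	id0040	-1.6144	-3.1671
id0041	id0041	-0.3344	0.1698
id0042	id0042	0.9796	2.6445
id0043	id0043	-1.0432	-3.6903
id0044	id0044	2.7884	4.7205
id0045	id0045	0.4597	-0.8182
id0046	id0046	-1.5667	-0.9352
id0047	id0047	3.2673	4.8843
id0048	id0048	1.8936	3.2739
id0049	id0049	-1.2621	-1.7834
id0050	id0050	-2.7634	-5.5183
id0051	id0051	-2.031	-2.1452
id0052	id0052	2.4231	2.2709
id0053	id0053	0.2278	0.4432
id0054	id0054	1.0033	0.3943
id0055	id0055	1.8996	2.5933
id0056	id0056	-2.1628	-2.0683
id0057	id0057	-0.2561	1.435
id0058	id0058	0.6299	2.074
id0059	id0059	0.4613	2.8437
id0060	id0060	-0.0664	0.8018
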