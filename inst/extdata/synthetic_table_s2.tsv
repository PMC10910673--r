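metabolite	cancer	variant_id	beta_exp	se_exp	beta_out	se_out	eaf	n_exp
O-methylcatechol sulfate	Lung cancer	rs1001	0.1198	0.01405	0.11884	0.0121	0.23	14296
O-methylcatechol sulfate	Lung cancer	rs1002	0.30675	0.01266	0.3249	0.0109	0.322	14296
O-methylcatechol sulfate	Lung cancer	rs1003	-0.11684	0.0126	-0.13154	0.01085	0.328	14296
O-methylcatechol sulfate	Lung cancer	rs1004	-0.11506	0.01279	-0.10731	0.01102	0.309	14296
O-methylcatechol sulfate	Colorectal cancer	rs2001	-0.25196	0.01802	-0.12951	0.01551	0.123	14296
O-methylcatechol sulfate	Colorectal cancer	rs2002	-0.36907	0.01228	-0.11212	0.01057	0.365	14296
O-methylcatechol sulfate	Colorectal cancer	rs2003	0.10212	0.01681	0.03928	0.01447	0.145	14296
O-methylcatechol sulfate	Colorectal cancer	rs2004	0.15969	0.01348	0.04157	0.0116	0.26	14296
O-methylcatechol sulfate	Colorectal cancer	rs2005	-0.09008	0.01289	-0.04307	0.0111	0.301	14296
O-methylcatechol sulfate	Colorectal cancer	rs2006	0.26888	0.01186	0.10069	0.01021	0.461	14296
O-methylcatechol sulfate	Colorectal cancer	rs2007	-0.10912	0.01294	-0.04161	0.01114	0.297	14296
O-methylcatechol sulfate	Colorectal cancer	rs2008	0.35831	0.01626	0.11562	0.014	0.157	14296
O-methylcatechol sulfate	Colorectal cancer	rs2009	-0.39352	0.01244	-0.13021	0.01071	0.346	14296
4-vinylphenol sulfate	Renal cell cancer	rs3001	0.28478	0.01765	-0.19191	0.0152	0.129	14296
4-vinylphenol sulfate	Renal cell cancer	rs3002	-0.24234	0.01186	0.18985	0.01021	0.462	14296
4-vinylphenol sulfate	Renal cell cancer	rs3003	0.15993	0.01235	-0.10621	0.01063	0.356	14296
4-vinylphenol sulfate	Renal cell cancer	rs3004	0.24921	0.01189	-0.14561	0.01023	0.45	14296
4-vinylphenol sulfate	Renal cell cancer	rs3005	-0.09158	0.01646	0.09415	0.01417	0.152	14296
4-vinylphenol sulfate	Renal cell cancer	rs3006	0.25478	0.01532	-0.1396	0.01319	0.182	14296
4-vinylphenol sulfate	Renal cell cancer	rs3007	-0.10686	0.01873	0.10514	0.01613	0.112	14296
4-vinylphenol sulfate	Renal cell cancer	rs3008	-0.13894	0.01385	0.10674	0.01192	0.24	14296
N6-succinyladenosine	Prostate cancer	rs4001	-0.34097	0.01423	-0.06506	0.01225	0.222	14296
N6-succinyladenosine	Prostate cancer	rs4002	0.32806	0.01186	0.0513	0.01021	0.465	14296
N6-succinyladenosine	Prostate cancer	rs4003	0.34172	0.01268	0.07397	0.01092	0.319	14296
N6-succinyladenosine	Prostate cancer	rs4004	0.38953	0.01321	0.05691	0.01138	0.277	14296
CMPF	Breast cancer	rs5001	-0.26174	0.01215	-0.04209	0.01046	0.386	14296
CMPF	Breast cancer	rs5002	0.13238	0.01362	0.02649	0.01173	0.252	14296
CMPF	Breast cancer	rs5003	0.25442	0.01186	0.05999	0.01021	0.461	14296
CMPF	Breast cancer	rs5004	-0.31679	0.01502	-0.0645	0.01293	0.192	14296
CMPF	Breast cancer	rs5005	0.25957	0.01418	0.0464	0.01221	0.224	14296
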