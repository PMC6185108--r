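feature_id	C1	C2	C3	C4	M1	M2	M3	M4
P01	5010	5011	5012	5013	5014	5015	5016	5017
P02	5020	5021	5022	5023	5024	5025	5026	5027
P03	5030	5031	NA	5033	5034	5035	5036	5037
P04	5040	5041	5042	5043	5044	5045	5046	5047
P05	NA	5051	5052	5053	NA	5055	5056	NA
P06	5060	5061	5062	5063	5064	5065	5066	5067
P07	NA	NA	NA	NA	NA	NA	NA	NA
P08	5080	5081	5082	5083	5084	NA	5086	5087
P09	5090	5091	5092	5093	5094	5095	5096	5097
P10	5100	5101	5102	5103	5104	5105	5106	5107
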