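feature_id	C1	C2	C3	C4	M1	M2	M3	M4
GP01:10	1010	1011	1012	1013	2010	2011	2012	2013
GP02:18	1020	1021	1022	NA	2020	2021	2022	2023
GP03:26	1030	1031	1032	NA	NA	NA	NA	NA
GP04:34	1040	1041	1042	1043	NA	NA	NA	NA
GP05:42	NA	NA	NA	NA	2050	2051	2052	NA
GP06:50	NA	NA	NA	NA	2060	2061	2062	2063
GP07:58	1070	1071	NA	NA	2070	2071	2072	2073
GP08:66	1080	NA	NA	NA	2080	NA	NA	NA
GP09:74	NA	NA	NA	NA	2090	2091	NA	NA
GP10:82	1100	1101	NA	NA	NA	NA	NA	NA
GP11:90	1110	1111	1112	1113	2110	NA	NA	NA
GP12:98	1120	1121	1122	NA	2120	2121	NA	NA
GP13:106	1130	1131	1132	1133	2130	2131	NA	NA
GP14:114	NA	NA	NA	NA	NA	NA	NA	NA
GP15:122	1150	1151	1152	NA	2150	2151	2152	NA
GP16:130	1160	NA	NA	NA	2160	2161	2162	2163
GP17:138	1170	1171	NA	NA	2170	2171	NA	NA
GP18:146	1180	1181	1182	1183	2180	2181	2182	NA
GP19:154	1190	1191	1192	NA	2190	NA	NA	NA
GP20:162	1200	1201	NA	NA	2200	2201	2202	NA
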