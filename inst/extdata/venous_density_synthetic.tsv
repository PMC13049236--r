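roi_id	name	venous_density
1	ROI_01	0.334
2	ROI_02	1.951
3	ROI_03	0.929
4	ROI_04	0.97
5	ROI_05	1.358
6	ROI_06	1.021
7	ROI_07	0.799
8	ROI_08	1.196
9	ROI_09	1.813
10	ROI_10	2.723
11	ROI_11	0.858
12	ROI_12	1.272
13	ROI_13	1.038
14	ROI_14	1.659
15	ROI_15	2.649
16	ROI_16	1.03
17	ROI_17	1.005
18	ROI_18	0.839
19	ROI_19	1.113
20	ROI_20	0.717
21	ROI_21	0.378
22	ROI_22	1.455
23	ROI_23	0.363
24	ROI_24	0.707
25	ROI_25	0.884
26	ROI_26	1.13
27	ROI_27	1.476
28	ROI_28	0.605
29	ROI_29	0.609
30	ROI_30	0.735
31	ROI_31	0.679
32	ROI_32	1.735
33	ROI_33	0.915
34	ROI_34	1.315
35	ROI_35	0.379
36	ROI_36	0.447
37	ROI_37	1.014
38	ROI_38	1.107
39	ROI_39	1.152
40	ROI_40	0.582
41	ROI_41	1.924
42	ROI_42	0.712
43	ROI_43	0.632
44	ROI_44	1.523
45	ROI_45	0.962
46	ROI_46	1.888
47	ROI_47	0.329
48	ROI_48	0.52
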