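library	a	b	r_squared	total_detected	slope_final	final_reads
COT	11629	35034	0.9948	10873	0.0043	272402
E	13062	18865	0.9989	11566	0.0128	120126
L	12734	20070	0.9987	11631	0.0081	157921
EPI	13662	24062	0.998	12736	0.0073	188193
LVN.5	13109	30514	0.9968	12283	0.0045	267966
LVN.1	13715	20362	0.9976	13298	0.0031	277888
LVN.2	13559	19746	0.9982	12981	0.0042	233790
LVN.3	12718	16929	0.9995	11465	0.0122	115751
LVN.4	13359	19496	0.9986	12670	0.0044	223596
FLO	12382	18261	0.9998	10774	0.0176	95097
HYP	13741	23566	0.997	13071	0.0042	255310
LVR.1	10087	46963	0.996	8515	0.0084	191205
all	16314	35169	0.9921	17104	0.0001	2399245
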