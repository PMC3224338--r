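reference	accession	ref_length	n_reads_mapped	n_identical	n_putative_variant	n_putative_error
LHCb1	gi|56809378	801	56517	9	131	779
LHCb2	gi|56809380	798	15370	28	9	768
CCBP	gi|141448063	922	10616	609	18	296
Ran1	gi|123192430	666	6488	363	8	300
RuBP	gi|169152	674	651	182	68	475
ApxI	gi|169042	3625	32	1367	8	99
ek-oxidase	gi|37954113	1797	1474	1749	20	25
Fed-1	gi|169086	1995	35	1360	1	87
HMG1	gi|436423	807	6	670	5	124
plastocyanin	gi|20845	1505	107	1050	2	453
G3bh	gi|2316017	4248	3	3577	0	1
bHLH	gi|308084332	11892	0	0	NA	NA
SBEII	gi|510546	2919	14	2186	20	18
SGR	gi|156713218	792	1	787	4	1
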