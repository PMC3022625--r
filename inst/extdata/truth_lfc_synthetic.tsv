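gene_id	baseline	lfc
ACT1	8	0
YPL122C	2	1
YNR030W	4	2
YDR343C	8	1
YGR088W	16	2
YPR149W	1	1
YCL040W	2	2
YBR054W	4	1
YNR001C	8	2
YDR533C	16	1
YDL222C	1	2
YML123C	2	-1
YEL046C	4	-2
YLR180W	8	-1
YLR355C	16	-2
YLR419W	1	-1
YLR300W	2	-2
YNL300W	4	-1
YLR372W	8	-2
YAL059W	16	-1
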