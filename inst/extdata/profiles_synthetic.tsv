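sample_id	gene_id	weight
untreated	ACT1	0.0610687022900763
untreated	YPL122C	0.0152671755725191
untreated	YNR030W	0.0305343511450382
untreated	YDR343C	0.0610687022900763
untreated	YGR088W	0.122137404580153
untreated	YPR149W	0.00763358778625954
untreated	YCL040W	0.0152671755725191
untreated	YBR054W	0.0305343511450382
untreated	YNR001C	0.0610687022900763
untreated	YDR533C	0.122137404580153
untreated	YDL222C	0.00763358778625954
untreated	YML123C	0.0152671755725191
untreated	YEL046C	0.0305343511450382
untreated	YLR180W	0.0610687022900763
untreated	YLR355C	0.122137404580153
untreated	YLR419W	0.00763358778625954
untreated	YLR300W	0.0152671755725191
untreated	YNL300W	0.0305343511450382
untreated	YLR372W	0.0610687022900763
untreated	YAL059W	0.122137404580153
treated	ACT1	0.0368663594470046
treated	YPL122C	0.0184331797235023
treated	YNR030W	0.0737327188940092
treated	YDR343C	0.0737327188940092
treated	YGR088W	0.294930875576037
treated	YPR149W	0.00921658986175115
treated	YCL040W	0.0368663594470046
treated	YBR054W	0.0368663594470046
treated	YNR001C	0.147465437788018
treated	YDR533C	0.147465437788018
treated	YDL222C	0.0184331797235023
treated	YML123C	0.00460829493087558
treated	YEL046C	0.00460829493087558
treated	YLR180W	0.0184331797235023
treated	YLR355C	0.0184331797235023
treated	YLR419W	0.00230414746543779
treated	YLR300W	0.00230414746543779
treated	YNL300W	0.00921658986175115
treated	YLR372W	0.00921658986175115
treated	YAL059W	0.0368663594470046
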