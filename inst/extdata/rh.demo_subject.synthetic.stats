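# Synthetic example in FreeSurfer mris_anatomical_stats table layout
# (fabricated values for documentation and format tests; not real data)
# hemi rh
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg
7AL  100  596.3  1490.8  2.400
VIP  200  404.7  1011.8  2.400
LIPd  300  1368.1  3420.2  2.400
IP1  400  1068.4  2671.0  2.400
IP2  500  1305.4  3263.5  2.400
11l  600  755.1  1887.8  2.400
P007  700  307.9  769.8  2.400
P008  800  1358.9  3397.2  2.400
P009  900  301.5  753.8  2.400
P010  1000  560.9  1402.2  2.400
P011  1100  950.1  2375.2  2.400
P012  1200  720.6  1801.5  2.400
P013  1300  750.8  1877.0  2.400
P014  1400  1009.1  2522.8  2.400
P015  1500  352.6  881.5  2.400
P016  1600  877.0  2192.5  2.400
P017  1700  1198.3  2995.8  2.400
P018  1800  1371.0  3427.5  2.400
P019  1900  1088.8  2722.0  2.400
P020  2000  1570.7  3926.8  2.400
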