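# Synthetic example in FreeSurfer mris_anatomical_stats table layout
# (fabricated values for documentation and format tests; not real data)
# hemi lh
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg
7AL  100  1060.1  2650.2  2.400
VIP  200  447.9  1119.8  2.400
LIPd  300  1189.5  2973.8  2.400
IP1  400  1590.3  3975.8  2.400
IP2  500  995.5  2488.8  2.400
11l  600  1556.6  3891.5  2.400
P007  700  1172.9  2932.2  2.400
P008  800  683.0  1707.5  2.400
P009  900  765.9  1914.8  2.400
P010  1000  527.9  1319.8  2.400
P011  1100  1013.5  2533.8  2.400
P012  1200  957.1  2392.8  2.400
P013  1300  552.0  1380.0  2.400
P014  1400  1128.0  2820.0  2.400
P015  1500  1194.1  2985.2  2.400
P016  1600  1132.2  2830.5  2.400
P017  1700  765.3  1913.2  2.400
P018  1800  433.4  1083.5  2.400
P019  1900  427.1  1067.8  2.400
P020  2000  537.8  1344.5  2.400
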