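mutation	expected_label	ddssv	source
H228T	beneficial	-186.18	curated
V174C/A404V/L441F	beneficial	-246.22	curated
H184F	beneficial	100.37	curated
P172L	beneficial	-6.29	curated
P172L/F250A	beneficial	-6.29	curated
L167W	beneficial	-602.80	curated
L167W/P172L	beneficial	-615.46	curated
L167W/P172L/P338F	beneficial	-615.46	curated
V168Y	not_beneficial	330.56	curated
F225S	not_beneficial	-365.07	curated
Y308F	not_beneficial	34.19	curated
Y308A	not_beneficial	-108.62	curated
I207V	beneficial	-71.56	curated
N218H	beneficial	-230.61	curated
N273V	not_beneficial	-55.26	curated
F252I	not_beneficial	86.70	curated
F252W	not_beneficial	129.97	curated
F252Y	not_beneficial	37.86	curated
M284N	not_beneficial	-127.35	curated
H276M	not_beneficial	-501.32	curated
V173C	not_beneficial	13.59	curated
M177L	not_beneficial	20.86	curated
D229N	not_beneficial	18.11	curated
H231D	not_beneficial	-54.22	curated
E96K	beneficial	-31.08	curated
N223G	not_beneficial	39.37	curated
N223Q	not_beneficial	264.34	curated
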