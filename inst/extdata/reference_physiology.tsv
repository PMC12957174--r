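organ	volume_L	flow_frac_co
lung	0.53	1.000
adipose	15.00	0.050
bone	10.60	0.050
brain	1.45	0.120
gut	1.65	0.140
heart	0.33	0.040
kidney	0.31	0.170
liver	1.80	0.065
muscle	29.00	0.170
skin	3.30	0.050
spleen	0.15	0.030
arterial	1.80	NA
venous	3.40	NA
portal	0.60	NA
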