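gene	in_silico_group	de_male_vs_female
dmY/dmrt1a	SD7	up_in_male
gsdf	SD17	up_in_male
amhY	SD4	up_in_male
amhr2	SD1	no_expression
sdY	NA	NA
sox3Y	SD18	up_in_female
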