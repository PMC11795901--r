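#population-model	v1
#n_pop	1000
#label	synthetic background corpus (1000 records)
#section	freetext
screening	6
breast	25
cancer	180
women	120
study	700
patients	650
recall	12
cells	400
treatment	300
risk	250
#section	mesh
Humans	850
Female	400
Breast Neoplasms	20
Mass Screening	8
Neoplasms	150
Mammography	5
#section	qualifier
diagnosis	120
therapy	160
epidemiology	90
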