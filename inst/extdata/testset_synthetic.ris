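TY  - JOUR
AN  - 100001
AU  - Author 1
TI  - screening screening screening study patients
AB  - mammography mammography breast breast cancer cancer women recall
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mammography
KW  - Early Detection of Cancer
ER  - 

TY  - JOUR
AN  - 100002
AU  - Author 2
TI  - women
AB  - screening screening screening breast breast cancer cancer cancer patients patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
KW  - Breast Neoplasms/therapy
ER  - 

TY  - JOUR
AN  - 100003
AU  - Author 3
TI  - mammography breast breast study patients patients
AB  - screening screening screening cancer cancer women
PY  - 2022
KW  - Humans
KW  - Female
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
ER  - 

TY  - JOUR
AN  - 100004
AU  - Author 4
AB  - screening screening screening breast breast breast breast study recall
PY  - 2022
KW  - Humans
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
KW  - Mammography
KW  - Breast Neoplasms/therapy
ER  - 

TY  - JOUR
AN  - 100005
AU  - Author 5
TI  - screening screening screening screening mammography mammography breast breast recall
AB  - study patients patients patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Early Detection of Cancer
KW  - Breast Neoplasms/therapy
ER  - 

TY  - JOUR
AN  - 100006
AU  - Author 6
TI  - breast breast breast breast patients recall
AB  - screening screening mammography cancer cancer cancer
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mass Screening
KW  - Breast Neoplasms/therapy
ER  - 

TY  - JOUR
AN  - 100007
AU  - Author 7
TI  - screening screening
AB  - mammography mammography cancer women patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mass Screening
KW  - Mammography
KW  - Early Detection of Cancer
KW  - Breast Neoplasms/therapy
KW  - my lab keyword
ER  - 

TY  - JOUR
AN  - 100008
AU  - Author 8
TI  - screening screening mammography mammography
AB  - breast breast cancer recall
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mass Screening
KW  - Mammography
KW  - Breast Neoplasms/therapy
KW  - my lab keyword
ER  - 

TY  - JOUR
AN  - 100009
AU  - Author 9
TI  - mammography cancer cancer cancer cancer patients
AB  - screening women women
PY  - 2022
KW  - Humans
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
KW  - Mammography
KW  - Breast Neoplasms/therapy
KW  - my lab keyword
ER  - 

TY  - JOUR
AN  - 100010
AU  - Author 10
TI  - breast cancer cancer women
AB  - screening study patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mammography
KW  - Early Detection of Cancer
KW  - Breast Neoplasms/therapy
KW  - my lab keyword
ER  - 

TY  - JOUR
AN  - 100011
AU  - Author 11
TI  - cancer cancer cancer
AB  - screening mammography breast breast breast breast women women
PY  - 2022
KW  - Female
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
ER  - 

TY  - JOUR
AN  - 100012
AU  - Author 12
TI  - mammography cancer cancer
AB  - screening breast breast study
PY  - 2022
KW  - Humans
KW  - Female
KW  - Mammography
ER  - 

TY  - JOUR
AN  - 100013
AU  - Author 13
AB  - breast cancer cancer cancer women women women women patients
PY  - 2022
KW  - Humans
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
ER  - 

TY  - JOUR
AN  - 100014
AU  - Author 14
TI  - mammography mammography
AB  - screening cancer cancer women women study
PY  - 2022
KW  - Humans
KW  - Female
KW  - Early Detection of Cancer
ER  - 

TY  - JOUR
AN  - 100015
AU  - Author 15
TI  - cancer cancer women women
AB  - screening screening mammography mammography breast breast breast study study patients patients patients patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Breast Neoplasms/diagnosis
KW  - my lab keyword
ER  - 

TY  - JOUR
AN  - 100016
AU  - Author 16
TI  - breast breast
AB  - screening screening mammography mammography cancer women women study patients
PY  - 2022
KW  - Humans
KW  - Mass Screening
ER  - 

TY  - JOUR
AN  - 100017
AU  - Author 17
TI  - women recall
AB  - screening screening cancer cancer study
PY  - 2022
KW  - Humans
KW  - Female
KW  - Breast Neoplasms/diagnosis
ER  - 

TY  - JOUR
AN  - 100018
AU  - Author 18
TI  - screening screening mammography breast recall recall
AB  - cancer cancer women study patients patients
PY  - 2022
KW  - Humans
KW  - Female
KW  - Breast Neoplasms/diagnosis
KW  - Mass Screening
ER  - 
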