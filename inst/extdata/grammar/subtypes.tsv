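# phrase	positive	abbrev
invasive ductal carcinoma	1	idc
invasive lobular carcinoma	1	ilc
invasive mammary carcinoma	1
tubular carcinoma	1
mucinous carcinoma	1
cribriform carcinoma	1
intraductal papillary carcinoma	1
papillary carcinoma	1
microinvasive carcinoma	1
microinvasive ductal carcinoma	1
ductal carcinoma in situ	1	dcis
lymphoma	1
lobular carcinoma in situ	0	lcis
atypical ductal hyperplasia	0	adh
atypical lobular hyperplasia	0	alh
usual ductal hyperplasia	0	udh
flat epithelial atypia	0
sclerosing adenosis	0
intraductal papilloma	0
fibroadenoma	0
columnar cell change	0
apocrine metaplasia	0
fibrocystic changes	0
radial scar	0
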