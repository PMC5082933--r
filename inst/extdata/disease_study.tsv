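code	name
BRCA	Breast invasive carcinoma
GBM	Glioblastoma multiforme
OV	Ovarian serous cystadenocarcinoma
LUAD	Lung adenocarcinoma
PRAD	Prostate adenocarcinoma
COAD	Colon adenocarcinoma
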