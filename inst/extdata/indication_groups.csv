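keyword,group
lung,Lung cancer
bronch,Lung cancer
mesothelioma,Mesothelioma
melanoma,Melanoma
renal,Tumors of urinary system
kidney,Tumors of urinary system
bladder,Tumors of urinary system
urothelial,Tumors of urinary system
urinary,Tumors of urinary system
prostat,Tumors of urinary system
head and neck,Head and neck cancer
laryn,Head and neck cancer
pharyn,Head and neck cancer
oral,Head and neck cancer
lymphoma,Hematological cancer and lymphoma
leukaemia,Hematological cancer and lymphoma
leukemia,Hematological cancer and lymphoma
myeloma,Hematological cancer and lymphoma
hodgkin,Hematological cancer and lymphoma
ovarian,Tumors of female reproductive organs
cervix,Tumors of female reproductive organs
cervical,Tumors of female reproductive organs
endometri,Tumors of female reproductive organs
uterine,Tumors of female reproductive organs
gastric,Gastrointestinal cancer
colorect,Gastrointestinal cancer
colon,Gastrointestinal cancer
rectal,Gastrointestinal cancer
oesophag,Gastrointestinal cancer
esophag,Gastrointestinal cancer
pancrea,Gastrointestinal cancer
breast,Breast cancer
hepatocellular,Hepatocellular carcinoma
liver,Hepatocellular carcinoma
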