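submitted_string	code
invasive ductal carcinoma	BREAST_IDC
invasive lobular carcinoma	BREAST_ILC
lung adenocarcinoma	LUNG_NSC_LUAD
lung squamous cell carcinoma	LUNG_NSC_LUSC
small cell lung cancer	LUNG_SC
colon adenocarcinoma	COLORECT_COLON
rectal adenocarcinoma	COLORECT_RECTUM
pancreatic ductal adenocarcinoma	PANCREAS_DUCTAL
hepatocellular carcinoma	LIVER_HCC
clear cell renal cell carcinoma	KIDNEY_CLEARCELL
high grade serous ovarian carcinoma	OVARY_HGSOC
glioblastoma	GLIOMA_GBM
cutaneous melanoma	SKIN_MEL_CUTANEOUS
prostate adenocarcinoma	PROSTATE
urothelial carcinoma	BLADDER
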