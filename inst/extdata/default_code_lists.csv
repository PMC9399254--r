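code,system,category
T40,ICD10,nonfatal_overdose
T43.6,ICD10,nonfatal_overdose
X40,ICD10,fatal_overdose
X41,ICD10,fatal_overdose
X42,ICD10,fatal_overdose
X43,ICD10,fatal_overdose
X44,ICD10,fatal_overdose
T40,ICD10,overdose_history
T43.6,ICD10,overdose_history
X60,ICD10,self_harm_history
X78,ICD10,self_harm_history
BUP-PATCH-5,PRODUCT,analgesia_exclusion
BUP-PATCH-10,PRODUCT,analgesia_exclusion
BUP-SL-200MCG,PRODUCT,analgesia_exclusion
MET-LINCTUS,PRODUCT,analgesia_exclusion
MET-INJ-PAIN,PRODUCT,analgesia_exclusion
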