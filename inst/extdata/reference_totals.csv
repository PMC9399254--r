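quantity,value
n_patients,20898
person_years,83856
nonfatal_overdose_admissions,12973
patients_with_overdose,4512
wrr_bup_vs_meth,0.39
wrr_bup_vs_meth_low,0.38
wrr_bup_vs_meth_high,0.41
wrr_out_vs_in,1.51
wrr_out_vs_in_low,1.42
wrr_out_vs_in_high,1.60
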