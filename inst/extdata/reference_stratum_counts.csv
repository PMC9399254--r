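measure,stratum,group,person_years,events
event_rate,status,in,25206,3930
event_rate,status,out,33170,7478
event_rate,window,in_1_4,3598,1861
event_rate,window,in_gt4,21608,2069
event_rate,window,out_1_4,3492,3639
event_rate,window,out_gt4,29677,3839
event_rate,modality_all,methadone,64232,11360
event_rate,modality_all,buprenorphine,19623,1613
event_rate,modality_in,methadone,25760,4158
event_rate,modality_in,buprenorphine,5560,385
event_rate,modality_out,methadone,38472,7202
event_rate,modality_out,buprenorphine,14063,1228
incidence,status,in,21798,1602
incidence,status,out,27219,2665
incidence,window,in_1_4,2904,319
incidence,window,in_gt4,18894,1283
incidence,window,out_1_4,2641,516
incidence,window,out_gt4,24578,2149
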