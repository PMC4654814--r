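sample_id,ABCA1_T1,APOA4_T1,CETP_T1,SRBI_T1
123,1,0.56,0.99,1.06
157,0.75,0.98,0.65,0.98
209,0.7,1.12,0.92,0.77
367,0.95,0.55,0.93,1.0
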