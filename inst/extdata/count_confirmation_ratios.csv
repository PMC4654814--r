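sample_id,ABCA1,APOA4,CETP
123,,1.10,
157,,,0.58
209,1.06,,
367,,1.04,
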