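Formula_1	herb_4|herb_2|herb_9|herb_6
Formula_2	herb_4|herb_8|herb_1|herb_10|herb_2|herb_5|herb_3|herb_7
Formula_3	herb_1|herb_6
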