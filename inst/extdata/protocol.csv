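parameter,arm,stage,item,value
tare_procedures,TARE,intermediate,,1.1
tare_procedures,TARE,advanced,,1.02
sorafenib_duration,sorafenib,intermediate,,7.5
sorafenib_duration,sorafenib,advanced,,8.1
second_line_share,TARE,intermediate,sorafenib,0.303
second_line_share,TARE,intermediate,tace,0.183
second_line_share,TARE,intermediate,rfa_pei_resection,0.055
second_line_share,TARE,advanced,sorafenib,0.20
second_line_share,TARE,advanced,tace,0.022
second_line_share,TARE,advanced,radiotherapy,0.022
second_line_share,sorafenib,intermediate,tace,0.066
second_line_share,sorafenib,intermediate,rfa_pei_resection,0.105
second_line_share,sorafenib,advanced,tace,0.026
second_line_share,sorafenib,advanced,rfa_pei_resection,0.013
transplant_share,TARE,intermediate,,0.037
decompensation_rate,TARE,intermediate,,0.194
decompensation_rate,TARE,advanced,,0.43
decompensation_rate,sorafenib,intermediate,,0.174
decompensation_rate,sorafenib,advanced,,0.31
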