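label,onset_s,duration_s
lights-off,60,0
lm-left,310.5,1.8
lm-right,310.9,2.1
lm-left,335.2,2.4
lm-left,358.7,1.6
lm-right,359,1.2
lm-left,382.1,2
apnea-obstructive,1205.4,22.5
hypopnea,1310,18.75
lm-left,1333.6,3.1
arousal,1329.2,9.5
desaturation,1352,24
lm-right,2410.3,1.1
lights-on,3660,0
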