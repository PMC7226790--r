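strain,eye_id,day,cd4_count
B10.RIII,B10.RIII_eye01,0,12
B10.RIII,B10.RIII_eye01,17,18250
C57BL.6,C57BL.6_eye03,21,7421
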