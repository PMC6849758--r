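pop,exposure,adaptive,neutral,overall,range_shift,risk
Lisboa,1,-,0,-,+,Low
Bizkaia,1,++,-,+,+,Low
Granada,2,-,0,-,-,Medium
Girona,3,+,-,0,+,Medium
Valladolid,3,-,-,-,-,Medium-high
Albacete,4,-,-,-,-,Medium-high
Valencia,4,++,-,+,-,High
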