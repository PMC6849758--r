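pop,region,tmax_now,rain_now,suit_now,tmax_future,rain_future,suit_future,suitable_now,suitable_future
Lisboa,Iberia,25.3,36,100,28.6,28,80,TRUE,TRUE
Bizkaia,Iberia,23.6,225,38,29.9,120,40,TRUE,TRUE
Girona,Iberia,25.6,159,76,32.1,90,7,TRUE,FALSE
Granada,Iberia,30.0,45,80,36.9,39,37,TRUE,TRUE
Albacete,Iberia,31.6,61,34,40.4,27,17,TRUE,FALSE
Valladolid,Iberia,29.3,65,56,38.4,34,41,TRUE,TRUE
Valencia,Iberia,28.5,87,44,35.6,42,5,TRUE,FALSE
Devon,England,19.8,171,90,25.5,107,95,TRUE,TRUE
Dorset,England,20.8,164,60,27.4,98,63,TRUE,TRUE
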