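model,objective function/constraint,max/min,min,max,unit
SAscore,objective function,min,,,
krafft_point,constraint,,0,inf,degC
surface_tension,constraint,,20,40,mN/m
logCMC,objective function,min,,,log10 uM
logLC50,constraint,,0,inf,log10 mg/L
biodegradability,objective function,max,,,
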