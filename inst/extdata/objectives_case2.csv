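model,objective function/constraint,max/min,min,max,unit
SAscore,constraint,,0,4.5,
krafft_point,constraint,,0,inf,degC
surface_tension,constraint,,20,35,mN/m
logCMC,objective function,min,,,log10 uM
logLC50,objective function,max,,,log10 mg/L
biodegradability,constraint,,0.6,1,
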