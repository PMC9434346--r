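metric,IRF,SRF,SHRM,PED,EZ,ELM
accuracy,0.989,0.976,0.951,0.857,0.930,0.873
sensitivity,0.813,0.887,0.798,0.886,0.934,0.918
specificity,0.998,0.998,0.996,0.996,0.858,0.688
dice,0.949,0.892,0.810,0.840,,
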