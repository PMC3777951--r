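signal_type,condition,tp,fp,tn,fn,ppv_printed,sensitivity_printed,specificity_printed,printed_sensitivity_matches_counts
arrhythmogenic,E-4031 10 nM,141,0,9,0,100,100,100,TRUE
arrhythmogenic,E-4031 100 nM,281,3,24,2,98.94,99.34,88.89,FALSE
arrhythmogenic,E-4031 700 nM (a),59,3,24,0,95.16,100,88.89,TRUE
arrhythmogenic,E-4031 700 nM (b),22,2,51,0,91.67,100,96.23,TRUE
morphology_changing,E-4031 400 nM + Esmolol 84 uM,38,2,18,0,95,100,90,TRUE
morphology_changing,E-4031 700 nM + Esmolol 84 uM,37,2,71,2,94.87,94.87,97.26,TRUE
morphology_changing,E-4031 700 nM + Esmolol 168 uM,37,1,167,0,97.36,100,99.41,TRUE
morphology_changing,E-4031 1000 nM + Esmolol 168 uM,44,1,20,0,97.78,100,95.24,TRUE
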