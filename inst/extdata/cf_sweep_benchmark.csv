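signal_type,condition,cf,tp,fp,tn,fn,ppv_printed,sensitivity_printed,specificity_printed
normal,baseline,0.88,136,2,0,0,98.55,100,NA
normal,baseline,0.93,136,2,0,0,98.55,100,NA
normal,baseline,0.98,136,0,2,0,100,100,100
morphology_changing,E-4031 400 nM + Esmolol 84 uM,0.88,38,20,0,0,65.52,100,NA
morphology_changing,E-4031 400 nM + Esmolol 84 uM,0.93,38,6,14,0,86.36,100,70
morphology_changing,E-4031 400 nM + Esmolol 84 uM,0.98,38,2,18,0,95,100,90
arrhythmogenic,E-4031 700 nM,0.88,59,27,0,0,68.61,100,NA
arrhythmogenic,E-4031 700 nM,0.93,59,7,20,0,89.39,100,74.07
arrhythmogenic,E-4031 700 nM,0.98,59,3,24,0,95.16,100,88.89
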