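name,value
n_evaluations,270
n_children,218
n_questions,108
month18_alarms,9
month18_assessed,11
month24_alarms,4
month24_assessed,10
accuracy_pct,97.41
mean_assessments,1.24
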