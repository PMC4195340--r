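outcome,comparison,meanlog,sdlog
all-cause mortality,pharmacological vs placebo,-4.06,1.45
all-cause mortality,pharmacological vs pharmacological,-4.27,1.48
all-cause mortality,non-pharmacological,-3.93,1.51
semi-objective,pharmacological vs placebo,-3.02,1.85
semi-objective,pharmacological vs pharmacological,-3.23,1.88
semi-objective,non-pharmacological,-2.89,1.91
subjective,pharmacological vs placebo,-2.13,1.58
subjective,pharmacological vs pharmacological,-2.34,1.62
subjective,non-pharmacological,-2.00,1.64
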