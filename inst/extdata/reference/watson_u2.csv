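"condition","participant","target","u2"
"resting","P01","peak",0.059
"resting","P02","peak",0.054
"resting","P03","peak",0.57
"resting","P04","peak",0.078
"resting","P05","peak",0.887
"resting","P01","trough",1.125
"resting","P02","trough",0.273
"resting","P03","trough",0.099
"resting","P04","trough",0.207
"resting","P05","trough",0.064
"visual","P01","peak",0.054
"visual","P02","peak",0.031
"visual","P03","peak",0.046
"visual","P04","peak",0.064
"visual","P05","peak",0.093
"visual","P01","trough",0.338
"visual","P02","trough",0.951
"visual","P03","trough",0.554
"visual","P04","trough",0.069
"visual","P05","trough",0.151
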