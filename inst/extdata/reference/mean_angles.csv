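"condition","participant","method","target","mean_angle_rad"
"resting","P01","yw","peak",-0.475
"resting","P02","yw","peak",-0.228
"resting","P03","yw","peak",-0.35
"resting","P04","yw","peak",-0.271
"resting","P05","yw","peak",-0.216
"resting","P01","lms","peak",-0.154
"resting","P02","lms","peak",-0.108
"resting","P03","lms","peak",-0.369
"resting","P04","lms","peak",-0.337
"resting","P05","lms","peak",-0.333
"resting","P01","yw","trough",-3.009
"resting","P02","yw","trough",2.821
"resting","P03","yw","trough",2.923
"resting","P04","yw","trough",2.92
"resting","P05","yw","trough",2.872
"resting","P01","lms","trough",2.58
"resting","P02","lms","trough",2.761
"resting","P03","lms","trough",2.956
"resting","P04","lms","trough",2.613
"resting","P05","lms","trough",2.827
"visual","P01","yw","peak",0.478
"visual","P02","yw","peak",-0.481
"visual","P03","yw","peak",-0.169
"visual","P04","yw","peak",-0.655
"visual","P05","yw","peak",-0.883
"visual","P01","lms","peak",0.158
"visual","P02","lms","peak",-0.407
"visual","P03","lms","peak",-0.117
"visual","P04","lms","peak",-0.603
"visual","P05","lms","peak",-0.657
"visual","P01","yw","trough",0.708
"visual","P02","yw","trough",-2.03
"visual","P03","yw","trough",2.643
"visual","P04","yw","trough",-2.81
"visual","P05","yw","trough",-2.673
"visual","P01","lms","trough",0.449
"visual","P02","lms","trough",-1.09
"visual","P03","lms","trough",-2.112
"visual","P04","lms","trough",-3.067
"visual","P05","lms","trough",-2.167
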