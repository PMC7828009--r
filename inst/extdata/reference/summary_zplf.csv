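"condition","participant","method","target","n_trials","plf","zplf"
"resting","P01","yw","peak",3598,0.057,11.872
"resting","P02","yw","peak",3491,0.104,37.831
"resting","P03","yw","peak",3192,0.09,26.283
"resting","P04","yw","peak",3230,0.101,33.569
"resting","P05","yw","peak",3326,0.146,71.307
"resting","P01","lms","peak",3156,0.059,11.102
"resting","P02","lms","peak",3093,0.103,32.895
"resting","P03","lms","peak",3038,0.171,89.706
"resting","P04","lms","peak",3089,0.125,48.528
"resting","P05","lms","peak",3159,0.122,47.381
"resting","P01","yw","trough",3710,0.019,1.432
"resting","P02","yw","trough",3433,0.075,19.778
"resting","P03","yw","trough",3099,0.155,74.474
"resting","P04","yw","trough",3268,0.146,70.241
"resting","P05","yw","trough",3340,0.155,80.566
"resting","P01","lms","trough",3276,0.047,7.378
"resting","P02","lms","trough",3075,0.126,51.678
"resting","P03","lms","trough",2993,0.149,66.55
"resting","P04","lms","trough",3053,0.107,35.5
"resting","P05","lms","trough",3139,0.133,55.752
"visual","P01","yw","peak",3780,0.204,158.59
"visual","P02","yw","peak",3772,0.166,105.1
"visual","P03","yw","peak",3630,0.176,112.73
"visual","P04","yw","peak",3745,0.194,142.02
"visual","P05","yw","peak",3774,0.224,190.26
"visual","P01","lms","peak",3671,0.264,255.83
"visual","P02","lms","peak",3553,0.207,153.43
"visual","P03","lms","peak",3420,0.107,39.5
"visual","P04","lms","peak",3762,0.15,85.397
"visual","P05","lms","peak",3549,0.162,93.699
"visual","P01","yw","trough",3788,0.062,14.76
"visual","P02","yw","trough",3776,0.078,23.016
"visual","P03","yw","trough",3760,0.037,5.326
"visual","P04","yw","trough",3472,0.141,69.912
"visual","P05","yw","trough",3776,0.035,4.871
"visual","P01","lms","trough",3646,0.302,333.357
"visual","P02","lms","trough",3575,0.047,8.146
"visual","P03","lms","trough",3385,0.071,17.461
"visual","P04","lms","trough",3461,0.193,128.927
"visual","P05","lms","trough",3588,0.17,103.984
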