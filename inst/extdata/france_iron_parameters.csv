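gender,age_class,status,pop,meanlog,meanlog_lo,meanlog_hi,sdlog,sdlog_lo,sdlog_hi,req_mean,req_sd,prop_ida,hb_mean,hb_sd,thr_mild,thr_moderate,thr_severe
male,3-6,not_applicable,1571427,-0.21,-0.26,-0.17,0.31,0.27,0.36,0.5,0.1,0.147,12.8,1,10.9,9.9,7
male,7-11,not_applicable,1925359,0.06,0.01,0.09,0.28,0.26,0.31,0.8,0.16,0,13.3,1,11.4,10.9,8
male,12-17,not_applicable,2352805,0.62,0.59,0.66,0.34,0.31,0.36,1.27,0.25,0,13.9,1,11.9,10.9,9
male,18-24,not_applicable,2788141,0.52,0.46,0.58,0.37,0.33,0.42,0.97,0.38,0,15.5,0.8,12.9,10.9,8
male,25-44,not_applicable,8279094,0.75,0.71,0.78,0.31,0.29,0.34,0.97,0.38,0.26,15.3,1,12.9,10.9,8
male,45-64,not_applicable,7663979,0.74,0.71,0.78,0.32,0.3,0.34,0.97,0.38,0,15.3,1.1,12.9,10.9,8
male,65-74,not_applicable,2269631,0.79,0.75,0.84,0.34,0.31,0.37,0.97,0.38,0.42,14.9,1.9,12.9,10.9,8
female,3-6,premenopausal,1498259,-0.29,-0.34,-0.25,0.25,0.21,0.28,0.5,0.1,0.147,12.7,1,10.9,9.9,7
female,7-11,premenopausal,1829236,-0.07,-0.1,-0.03,0.29,0.26,0.31,0.8,0.16,0,13.4,1,11.4,10.9,8
female,12-14,premenopausal,1084687,0.43,0.38,0.48,0.34,0.3,0.37,1.13,0.23,0,13.4,1,11.9,10.9,8
female,15-17,premenopausal,1159862,0.4,0.36,0.45,0.36,0.33,0.4,1.41,0.76,0.5,13.4,1,11.9,10.9,8
female,18-24,premenopausal,2649398,0.52,0.46,0.58,0.37,0.33,0.42,1.41,0.76,0.05,13.5,1.5,11.9,10.9,8
female,25-44,premenopausal,7910584,0.59,0.56,0.62,0.35,0.33,0.37,1.41,0.76,0.09,13.5,1.4,11.9,10.9,8
female,45-64,premenopausal,2694011,0.67,0.62,0.73,0.39,0.35,0.43,1.41,0.76,0.1,13.7,1.1,11.9,10.9,8
female,25-44,postmenopausal,157425,0.19,-0.09,0.47,0.43,0.25,0.63,0.97,0.38,0,13.8,0.6,11.9,10.9,8
female,45-64,postmenopausal,5313189,0.64,0.6,0.68,0.38,0.35,0.41,0.97,0.38,0,13.8,0.9,11.9,10.9,8
female,65-74,postmenopausal,2712349,0.58,0.53,0.64,0.34,0.3,0.38,0.97,0.38,0.03,14,1.2,11.9,10.9,8
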