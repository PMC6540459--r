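activity_mbq,day,committed_dose_gy,sd_gy
5.74,2,1.31,0.36
5.74,3,1.65,0.07
5.74,5,2.42,0.14
5.74,7,2.97,0.31
5.74,14,4.3,0.84
6.66,2,1.62,0.57
6.66,3,2.16,0.57
6.66,5,3.23,0.20
6.66,7,4.2,0.34
6.66,14,5.61,0.70
7.65,2,2.16,0.17
7.65,3,2.76,0.45
7.65,5,4.44,0.41
7.65,7,5.68,0.24
7.65,14,6.81,1.84
9.28,2,2.98,0.14
9.28,3,4.41,0.32
9.28,5,5.98,0.32
9.28,7,8.37,1.05
9.28,14,12.31,1.86
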