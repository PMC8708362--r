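f_kHz,H_kA_per_m,x,PsM_W_per_g,DM_nm
100,20,0,31.69,17.4
100,20,0.05,21.14,11.5
100,20,0.1,11.85,9
100,20,0.2,6.45,7.2
100,20,0.4,3.96,6.2
100,20,0.67,3.05,5.9
100,20,0.8,3.03,5.9
100,20,1,4.11,6.7
250,20,0,77.6,16.7
250,20,0.05,48.95,11.1
250,20,0.1,26.59,8.6
250,20,0.2,14.23,6.9
250,20,0.4,8.66,NA
250,20,0.67,6.81,5.6
250,20,0.8,6.62,5.6
250,20,1,9.13,6.4
500,20,0,152.1,16.1
500,20,0.05,91.06,10.7
500,20,0.1,48.13,8.3
500,20,0.2,25.61,6.7
500,20,0.4,15.48,5.8
500,20,0.67,12.2,5.4
500,20,0.8,11.88,5.4
500,20,1,16.25,6.2
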