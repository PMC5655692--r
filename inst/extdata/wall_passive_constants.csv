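subject_id,layer,C1,a1,a2,a3,a4,a5,a6,R2_theta,R2_z,R2_r
Heart 1,wall,5.70,1.96,6.60,6.11,1.72,6.70,1.64,0.964,0.953,0.957
Heart 2,wall,3.64,3.02,9.60,5.70,1.19,8.20,1.61,0.974,0.968,0.968
Heart 3,wall,9.30,2.44,2.13,1.71,3.51,3.99,4.16,0.938,0.902,0.935
Heart 4,wall,4.72,4.81,3.30,8.63,10.30,5.02,2.81,0.921,0.932,0.937
Heart 5,wall,8.10,3.02,1.19,1.61,11.22,2.36,0.50,0.902,0.878,0.941
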