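subject_id,layer,C1,a1,a2,a3,a4,a5,a6,R2_theta,R2_z,R2_r
Heart 1,IM,6.29,2.79,1.64,5.49,2.50,3.20,2.11,0.999,0.999,0.999
Heart 2,IM,4.58,3.51,2.29,4.1,4.22,2.72,2.93,0.992,0.993,0.992
Heart 3,IM,7.21,5.23,2.56,5.67,4.21,4.56,2.44,0.998,0.990,0.986
Heart 4,IM,2.38,4.45,3.28,3.26,3.84,3.52,1.26,0.950,0.953,0.946
Heart 5,IM,4.41,6.63,5.68,4.13,4.63,5.72,6.19,0.908,0.891,0.910
Heart 6,IM,5.92,7.16,5.21,3.02,5.99,6.26,4.99,0.923,0.928,0.922
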