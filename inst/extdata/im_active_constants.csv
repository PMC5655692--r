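subject_id,layer,C2,b1,b2,b3,b_prime,R2_theta,R2_z,R2_r
Heart 1,IM,49.8,0.55,1.13,4.66,4.79,0.997,0.991,0.996
Heart 2,IM,47.5,0.43,0.92,1.60,6.28,0.995,0.997,0.996
Heart 3,IM,42.1,0.49,1.05,3.14,5.23,0.997,0.996,0.998
Heart 4,IM,40.3,0.64,1.32,7.37,3.96,0.955,0.989,0.942
Heart 5,IM,40.2,0.34,0.72,5.77,5.94,0.964,0.979,0.959
Heart 6,IM,45.2,0.58,1.22,3.20,4.86,0.966,0.982,0.962
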