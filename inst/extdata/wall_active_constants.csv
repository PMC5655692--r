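subject_id,layer,C2,b1,b2,b3,b_prime,R2_theta,R2_z,R2_r
Heart 1,wall,17.6,0.54,1.08,2.40,5.45,0.908,0.938,0.914
Heart 2,wall,12.3,0.25,0.41,1.02,9.43,0.912,0.936,0.951
Heart 3,wall,7.78,0.18,0.44,0.68,11.8,0.981,0.939,0.941
Heart 4,wall,11.1,0.79,1.21,3.72,4.06,0.920,0.899,0.902
Heart 5,wall,15.1,0.48,0.99,1.62,5.63,0.918,0.975,0.927
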