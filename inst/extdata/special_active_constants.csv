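key,C2,b1,b2,b3,b_prime,provenance
two_layer_IM,28.92,0.43,1.62,4.38,4.87,printed
fig4_wall,12.8,0.35,0.47,1.89,7.28,b1-b3 printed; C2 and b_prime completed with wall-mean values (synthetic defaults)
fig4_2d,12.8,0.12,0.18,NA,18.9,b1-b2 printed; C2 and b_prime are synthetic package defaults
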