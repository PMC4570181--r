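region_label,tissue,channel,mu_a,mu_s_prime,refractive_index
1,muscle,excitation,0.0052,1.08,1.37
2,lungs,excitation,0.0133,1.97,1.37
3,bone,excitation,0.0024,1.75,1.37
4,heart,excitation,0.0083,1.01,1.37
1,muscle,emission,0.0068,1.03,1.37
2,lungs,emission,0.0203,1.95,1.37
3,bone,emission,0.0035,1.61,1.37
4,heart,emission,0.0104,0.99,1.37
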