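region_label,tissue,channel,mu_a,mu_s_prime,refractive_index
1,adipose_bladder,emission,0.1017,1.2929,1.37
2,heart,emission,1.5477,1.1674,1.37
3,lungs,emission,4.6832,2.3271,1.37
4,liver_spleen,emission,9.2860,0.7786,1.37
5,stomach,emission,0.3082,1.6320,1.37
6,kidneys,emission,1.7334,2.7599,1.37
7,bone,emission,1.5233,3.0393,1.37
8,intestines,emission,0.2891,1.3548,1.37
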