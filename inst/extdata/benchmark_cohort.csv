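patient,n_seizures,interictal_hours,sensitivity_pct,precision_pct,fp_per_h,fp_pct,p_value
1,3,3,67,100,0.00,0.00,0.002
2,3,3,33,33,1.11,66.67,0.031
3,3,3,100,100,0.00,0.00,0.000
4,3,3,67,100,0.00,0.00,0.000
5,3,4,67,100,0.00,0.00,0.000
6,3,3,67,100,0.00,0.00,0.092
7,3,3,100,100,0.00,0.00,0.000
8,3,3,67,50,0.56,33.33,0.211
9,3,3,100,100,0.00,0.00,0.000
10,3,3,100,100,0.00,0.00,0.000
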