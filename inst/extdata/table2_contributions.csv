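layer,percent_contribution,permutation_importance
prec-10,37.3,1.4
srad-10,20.1,3.2
prec-11,9.9,4.6
bio-5,7.1,20.9
su_sym90,5.7,0.6
bio-3,5.7,1.6
prec-5,4.4,5.7
awc_class,3.5,1
bio-14,2.2,0.7
elev,2.1,18.4
t_oc,0.9,0.2
prec-4,0.4,39.7
bio-6,0.3,1.4
t_sand,0.2,0.4
t_clay,0.2,0.2
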