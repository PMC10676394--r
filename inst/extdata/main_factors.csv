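symbol,layer
X1,prec-4
X2,prec-5
X3,prec-10
X4,prec-11
X5,bio-14
X6,srad-10
X7,bio-5
X8,su_sym90
X9,awc_class
X10,elev
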