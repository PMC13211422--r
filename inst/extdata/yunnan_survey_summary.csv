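metal,min,max,mean,sd
Hg,0.01,0.31,0.03,0.02
Cd,0.03,3.54,0.17,0.14
Pb,5.30,157.00,25.01,11.03
As,0.79,57.20,7.46,4.29
Cr,28.40,365.00,85.91,22.77
Cu,6.67,1633.00,36.20,51.46
Ni,8.07,276.00,31.75,11.69
Zn,9.20,942.00,69.24,34.11
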