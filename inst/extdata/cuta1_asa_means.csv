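label,temperature_k,class,mean_nm2,sd_nm2
Ec0VV_6,400,hydrophobic,33.41,8.22
Ec0VV_6,450,hydrophobic,34.42,7.70
Ec0VV_6,300,hydrophobic,21.88,4.17
Ec0VV_6,400,hydrophilic,30.64,5.09
Ec0VV_6,450,hydrophilic,30.21,5.58
Ec0VV_6,300,hydrophilic,22.45,3.40
Ec0VV,400,hydrophobic,32.06,11.09
Ec0VV,450,hydrophobic,33.60,7.26
Ec0VV,300,hydrophobic,20.69,4.92
Ec0VV,400,hydrophilic,29.81,7.17
Ec0VV,450,hydrophilic,30.19,5.48
Ec0VV,300,hydrophilic,22.05,4.18
Ec0SH,400,hydrophobic,31.49,9.16
Ec0SH,450,hydrophobic,33.23,7.98
Ec0SH,300,hydrophobic,21.54,6.40
Ec0SH,400,hydrophilic,29.71,7.07
Ec0SH,450,hydrophilic,30.28,5.68
Ec0SH,300,hydrophilic,22.38,5.00
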