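group,parameter,median,q1,q3
benign,ac,0.506,0.402,0.623
benign,sos,1542,1525,1558.5
benign,esd,91.53,86.46,97.71
benign,esc,2.396,1.926,3.008
malignant,ac,0.666,0.609,0.731
malignant,sos,1565,1550,1579
malignant,esd,83.76,74,90.6
malignant,esc,2.6,1.987,3.733
idc,ac,0.664,0.616,0.73
idc,sos,1565,1552,1577
idc,esd,83.2,74,88.8
idc,esc,2.684,2.22,3.804
dcis,ac,0.682,0.577,0.877
dcis,sos,1577,1525,1579
dcis,esd,97,90.33,101.9
dcis,esc,3.148,2.525,3.733
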