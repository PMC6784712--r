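patient,night,predicted_category,predicted_ahi,predicted_severity
1,1,Abnormal,14.08,Mild
1,2,Abnormal,9.47,
2,1,Abnormal,10.38,Mild
2,2,Abnormal,11.52,
3,1,Abnormal,6.94,Mild
3,2,Normal,<5,
4,1,Abnormal,5.61,Mild
4,2,Normal,<5,
5,1,Abnormal,8.55,Mild
5,2,Abnormal,14.72,
6,1,Normal,<5,Mild
6,2,Abnormal,6.63,
8,1,Abnormal,13.07,Mild
8,2,Normal,<5,
9,1,Normal,<5,Normal
9,2,Normal,<5,
10,1,Normal,<5,Mild
10,2,Abnormal,5.27,
12,1,Abnormal,24.84,Severe
12,2,Normal,<5,
13,1,Normal,<5,Mild
13,2,Abnormal,9.00,
14,1,Normal,<5,Normal
14,2,Normal,<5,
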