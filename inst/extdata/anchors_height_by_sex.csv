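bin,lo,hi,sex,P5,P15,P50,P85,P95
50-59,50,60,male,5.4,5.8,6.7,7.5,8.0
50-59,50,60,female,5.2,5.7,6.6,7.3,7.8
60-69,60,70,male,6.3,6.8,7.6,8.5,9.0
60-69,60,70,female,6.2,6.7,7.6,8.4,8.9
70-79,70,80,male,7.2,7.7,8.6,9.5,10.0
70-79,70,80,female,7.2,7.7,8.6,9.4,10.0
80-89,80,90,male,7.9,8.5,9.4,10.3,10.8
80-89,80,90,female,7.9,8.4,9.3,10.2,10.8
90-99,90,100,male,8.5,9.1,10.1,11.0,11.5
90-99,90,100,female,8.5,9.0,9.9,10.8,11.4
100-109,100,110,male,9.1,9.7,10.7,11.6,12.2
100-109,100,110,female,9.0,9.5,10.4,11.4,12.1
110-119,110,120,male,9.6,10.2,11.3,12.3,12.9
110-119,110,120,female,9.4,9.9,10.9,12.0,12.7
120-129,120,130,male,10.1,10.7,11.8,12.9,13.5
120-129,120,130,female,9.8,10.4,11.5,12.6,13.3
130-139,130,140,male,10.5,11.2,12.3,13.4,14.1
130-139,130,140,female,10.3,11.0,12.1,13.3,14.0
140-149,140,150,male,11.1,11.8,13.0,14.1,14.8
140-149,140,150,female,11.0,11.7,12.9,14.2,14.9
150-159,150,160,male,11.7,12.4,13.6,14.8,15.5
150-159,150,160,female,11.7,12.4,13.8,15.1,15.9
160-169,160,170,male,12.3,13.1,14.4,15.6,16.3
160-169,160,170,female,12.3,13.2,14.6,16.0,16.8
170-179,170,180,male,13.0,13.8,15.1,16.4,17.2
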