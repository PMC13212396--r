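bin,lo,hi,sex,P5,P15,P50,P85,P95
0-0.24,0,0.25,male,5.1,5.6,6.6,7.5,8.0
0-0.24,0,0.25,female,4.9,5.5,6.3,7.2,7.6
0.25-0.49,0.25,0.5,male,5.8,6.3,7.3,8.3,8.8
0.25-0.49,0.25,0.5,female,5.6,6.2,7.1,7.9,8.4
0.5-0.74,0.5,0.75,male,6.4,7.0,7.9,8.9,9.5
0.5-0.74,0.5,0.75,female,6.3,6.8,7.7,8.6,9.1
0.75-0.99,0.75,1,male,6.9,7.5,8.4,9.4,10.0
0.75-0.99,0.75,1,female,6.8,7.3,8.2,9.2,9.7
1-1.49,1,1.5,male,7.5,8.0,9.0,10.0,10.5
1-1.49,1,1.5,female,7.4,7.9,8.8,9.7,10.3
1.5-1.99,1.5,2,male,8.0,8.5,9.5,10.4,11.0
1.5-1.99,1.5,2,female,7.9,8.4,9.3,10.2,10.8
2-2.99,2,3,male,8.4,9.0,10.0,10.9,11.5
2-2.99,2,3,female,8.3,8.8,9.6,10.6,11.2
3-3.99,3,4,male,8.8,9.4,10.4,11.3,11.9
3-3.99,3,4,female,8.7,9.1,10.1,11.1,11.7
4-4.99,4,5,male,9.2,9.7,10.7,11.7,12.3
4-4.99,4,5,female,8.9,9.4,10.4,11.4,12.1
5-5.99,5,6,male,9.6,10.2,11.2,12.3,12.8
5-5.99,5,6,female,9.3,9.8,10.8,11.9,12.6
6-6.99,6,7,male,10.0,10.6,11.7,12.7,13.4
6-6.99,6,7,female,9.6,10.2,11.3,12.4,13.1
7-7.99,7,8,male,10.0,10.7,11.8,12.9,13.6
7-7.99,7,8,female,9.7,10.3,11.4,12.5,13.2
8-8.99,8,9,male,10.2,10.9,12.1,13.2,13.9
8-8.99,8,9,female,9.9,10.6,11.7,13.0,13.7
9-9.99,9,10,male,10.3,11.1,12.3,13.6,14.3
9-9.99,9,10,female,10.4,11.1,12.3,13.6,14.4
10-10.99,10,11,male,10.6,11.4,12.7,14.1,14.8
10-10.99,10,11,female,10.8,11.6,12.9,14.3,15.0
11-11.99,11,12,male,11.1,11.9,13.3,14.6,15.4
11-11.99,11,12,female,11.2,12.0,13.3,14.7,15.5
12-12.99,12,13,male,11.4,12.3,13.7,15.1,15.9
12-12.99,12,13,female,11.5,12.3,13.7,15.0,15.8
13-13.99,13,14,male,11.9,12.7,14.1,15.4,16.2
13-13.99,13,14,female,11.8,12.6,14.0,15.3,16.1
14-14.99,14,15,male,12.3,13.1,14.5,15.8,16.6
14-14.99,14,15,female,12.0,12.8,14.2,15.6,16.4
15-15.99,15,16,male,12.5,13.4,14.8,16.1,16.9
15-15.99,15,16,female,12.0,12.9,14.4,15.8,16.7
16-16.99,16,17,male,12.8,13.6,15.1,16.5,17.3
16-16.99,16,17,female,12.0,12.8,14.4,15.9,16.8
17-17.99,17,18,male,13.0,13.8,15.3,16.7,17.4
17-17.99,17,18,female,12.1,12.9,14.5,16.1,17.1
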