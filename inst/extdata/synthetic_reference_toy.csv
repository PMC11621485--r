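sex,age_days,L,M,S,mode
female,0,1,50,0.04,length
female,1,1,50.1,0.04,length
female,2,1,50.2,0.04,length
female,3,1,50.3,0.04,length
female,4,1,50.4,0.04,length
female,5,1,50.5,0.04,length
female,6,1,50.6,0.04,length
female,7,1,50.7,0.04,length
female,8,1,50.8,0.04,length
female,9,1,50.9,0.04,length
female,10,1,51,0.04,length
female,11,1,51.1,0.04,length
female,12,1,51.2,0.04,length
female,13,1,51.3,0.04,length
female,14,1,51.4,0.04,length
female,15,1,51.5,0.04,length
female,16,1,51.6,0.04,length
female,17,1,51.7,0.04,length
female,18,1,51.8,0.04,length
female,19,1,51.9,0.04,length
female,20,1,52,0.04,length
female,21,1,52.1,0.04,length
female,22,1,52.2,0.04,length
female,23,1,52.3,0.04,length
female,24,1,52.4,0.04,length
female,25,1,52.5,0.04,length
female,26,1,52.6,0.04,length
female,27,1,52.7,0.04,length
female,28,1,52.8,0.04,length
female,29,1,52.9,0.04,length
female,30,1,53,0.04,length
female,31,1,53.1,0.04,length
female,32,1,53.2,0.04,length
female,33,1,53.3,0.04,length
female,34,1,53.4,0.04,length
female,35,1,53.5,0.04,length
female,36,1,53.6,0.04,length
female,37,1,53.7,0.04,length
female,38,1,53.8,0.04,length
female,39,1,53.9,0.04,length
female,40,1,54,0.04,length
female,41,1,54.1,0.04,length
female,42,1,54.2,0.04,length
female,43,1,54.3,0.04,length
female,44,1,54.4,0.04,length
female,45,1,54.5,0.04,length
female,46,1,54.6,0.04,length
female,47,1,54.7,0.04,length
female,48,1,54.8,0.04,length
female,49,1,54.9,0.04,length
female,50,1,55,0.04,length
female,51,1,55.1,0.04,length
female,52,1,55.2,0.04,length
female,53,1,55.3,0.04,length
female,54,1,55.4,0.04,length
female,55,1,55.5,0.04,length
female,56,1,55.6,0.04,length
female,57,1,55.7,0.04,length
female,58,1,55.8,0.04,length
female,59,1,55.9,0.04,length
female,60,1,56,0.04,length
female,61,1,56.1,0.04,length
female,62,1,56.2,0.04,length
female,63,1,56.3,0.04,length
female,64,1,56.4,0.04,length
female,65,1,56.5,0.04,length
female,66,1,56.6,0.04,length
female,67,1,56.7,0.04,length
female,68,1,56.8,0.04,length
female,69,1,56.9,0.04,length
female,70,1,57,0.04,length
female,71,1,57.1,0.04,length
female,72,1,57.2,0.04,length
female,73,1,57.3,0.04,length
female,74,1,57.4,0.04,length
female,75,1,57.5,0.04,length
female,76,1,57.6,0.04,length
female,77,1,57.7,0.04,length
female,78,1,57.8,0.04,length
female,79,1,57.9,0.04,length
female,80,1,58,0.04,length
female,81,1,58.1,0.04,length
female,82,1,58.2,0.04,length
female,83,1,58.3,0.04,length
female,84,1,58.4,0.04,length
female,85,1,58.5,0.04,length
female,86,1,58.6,0.04,length
female,87,1,58.7,0.04,length
female,88,1,58.8,0.04,length
female,89,1,58.9,0.04,length
female,90,1,59,0.04,length
female,91,1,59.1,0.04,length
female,92,1,59.2,0.04,length
female,93,1,59.3,0.04,length
female,94,1,59.4,0.04,length
female,95,1,59.5,0.04,length
female,96,1,59.6,0.04,length
female,97,1,59.7,0.04,length
female,98,1,59.8,0.04,length
female,99,1,59.9,0.04,length
female,100,1,60,0.04,length
male,0,1,50.6,0.04,length
male,1,1,50.7,0.04,length
male,2,1,50.8,0.04,length
male,3,1,50.9,0.04,length
male,4,1,51,0.04,length
male,5,1,51.1,0.04,length
male,6,1,51.2,0.04,length
male,7,1,51.3,0.04,length
male,8,1,51.4,0.04,length
male,9,1,51.5,0.04,length
male,10,1,51.6,0.04,length
male,11,1,51.7,0.04,length
male,12,1,51.8,0.04,length
male,13,1,51.9,0.04,length
male,14,1,52,0.04,length
male,15,1,52.1,0.04,length
male,16,1,52.2,0.04,length
male,17,1,52.3,0.04,length
male,18,1,52.4,0.04,length
male,19,1,52.5,0.04,length
male,20,1,52.6,0.04,length
male,21,1,52.7,0.04,length
male,22,1,52.8,0.04,length
male,23,1,52.9,0.04,length
male,24,1,53,0.04,length
male,25,1,53.1,0.04,length
male,26,1,53.2,0.04,length
male,27,1,53.3,0.04,length
male,28,1,53.4,0.04,length
male,29,1,53.5,0.04,length
male,30,1,53.6,0.04,length
male,31,1,53.7,0.04,length
male,32,1,53.8,0.04,length
male,33,1,53.9,0.04,length
male,34,1,54,0.04,length
male,35,1,54.1,0.04,length
male,36,1,54.2,0.04,length
male,37,1,54.3,0.04,length
male,38,1,54.4,0.04,length
male,39,1,54.5,0.04,length
male,40,1,54.6,0.04,length
male,41,1,54.7,0.04,length
male,42,1,54.8,0.04,length
male,43,1,54.9,0.04,length
male,44,1,55,0.04,length
male,45,1,55.1,0.04,length
male,46,1,55.2,0.04,length
male,47,1,55.3,0.04,length
male,48,1,55.4,0.04,length
male,49,1,55.5,0.04,length
male,50,1,55.6,0.04,length
male,51,1,55.7,0.04,length
male,52,1,55.8,0.04,length
male,53,1,55.9,0.04,length
male,54,1,56,0.04,length
male,55,1,56.1,0.04,length
male,56,1,56.2,0.04,length
male,57,1,56.3,0.04,length
male,58,1,56.4,0.04,length
male,59,1,56.5,0.04,length
male,60,1,56.6,0.04,length
male,61,1,56.7,0.04,length
male,62,1,56.8,0.04,length
male,63,1,56.9,0.04,length
male,64,1,57,0.04,length
male,65,1,57.1,0.04,length
male,66,1,57.2,0.04,length
male,67,1,57.3,0.04,length
male,68,1,57.4,0.04,length
male,69,1,57.5,0.04,length
male,70,1,57.6,0.04,length
male,71,1,57.7,0.04,length
male,72,1,57.8,0.04,length
male,73,1,57.9,0.04,length
male,74,1,58,0.04,length
male,75,1,58.1,0.04,length
male,76,1,58.2,0.04,length
male,77,1,58.3,0.04,length
male,78,1,58.4,0.04,length
male,79,1,58.5,0.04,length
male,80,1,58.6,0.04,length
male,81,1,58.7,0.04,length
male,82,1,58.8,0.04,length
male,83,1,58.9,0.04,length
male,84,1,59,0.04,length
male,85,1,59.1,0.04,length
male,86,1,59.2,0.04,length
male,87,1,59.3,0.04,length
male,88,1,59.4,0.04,length
male,89,1,59.5,0.04,length
male,90,1,59.6,0.04,length
male,91,1,59.7,0.04,length
male,92,1,59.8,0.04,length
male,93,1,59.9,0.04,length
male,94,1,60,0.04,length
male,95,1,60.1,0.04,length
male,96,1,60.2,0.04,length
male,97,1,60.3,0.04,length
male,98,1,60.4,0.04,length
male,99,1,60.5,0.04,length
male,100,1,60.6,0.04,length
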