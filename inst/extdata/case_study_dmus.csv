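node,dmu,o_som,o_mom,o_lom,s_som,s_mom,s_lom,d_som,d_mom,d_lom
manufacturer,A-S1,1.99,1.99,1.99,6.04,6.49,6.94,9.01,9.5,10
manufacturer,A-S2,1,1,1,8.02,9.01,10,9.01,9.5,10
manufacturer,A-S3,1,1,1,8.02,9.01,10,9.01,9.5,10
manufacturer,A-S4,1,1,1,8.02,9.01,10,9.01,9.5,10
manufacturer,A-S5,1.99,1.99,1.99,6.04,6.49,6.94,7.03,7.03,7.03
manufacturer,A-S6,5.05,5.5,5.95,6.04,6.49,6.94,7.03,7.03,7.03
manufacturer,A-M1,3.07,3.52,3.97,6.04,6.49,6.94,4.96,4.96,4.96
manufacturer,A-M2,3.07,3.52,3.97,6.04,6.49,6.94,4.96,4.96,4.96
manufacturer,A-M3,3.07,3.52,3.97,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,A-M4,3.07,3.52,3.97,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,A-M5,3.07,3.52,3.97,6.04,6.49,6.94,1,1,1
manufacturer,A-M6,1,1,1,6.04,6.49,6.94,1,1,1
manufacturer,A-M7,1.99,1.99,1.99,8.02,9.01,10,2.98,2.98,2.98
manufacturer,A-M8,1.99,1.99,1.99,6.04,6.49,6.94,1,1,1
manufacturer,A-M9,1.99,1.99,1.99,8.02,9.01,10,2.98,2.98,2.98
manufacturer,A-F1,3.07,3.52,3.97,6.04,6.49,6.94,1,1,1
manufacturer,B-S1,7.03,7.48,7.93,8.02,9.01,10,9.01,9.5,10
manufacturer,B-S2,5.05,5.5,5.95,8.02,9.01,10,9.01,9.5,10
manufacturer,B-S3,1,1,1,8.02,9.01,10,9.01,9.5,10
manufacturer,B-S4,3.07,3.52,3.97,8.02,9.01,10,9.01,9.5,10
manufacturer,B-S5,3.07,3.52,3.97,3.07,4.01,4.96,4.96,4.96,4.96
manufacturer,B-S6,5.05,5.5,5.95,6.04,6.49,6.94,4.96,4.96,4.96
manufacturer,B-M1,5.05,5.5,5.95,8.02,9.01,10,4.96,4.96,4.96
manufacturer,B-M2,1.99,1.99,1.99,6.04,6.49,6.94,4.96,4.96,4.96
manufacturer,B-M3,1.99,1.99,1.99,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,B-M4,1.99,1.99,1.99,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,B-M5,1.99,1.99,1.99,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,B-M6,1.99,1.99,1.99,8.02,9.01,10,7.03,7.03,7.03
manufacturer,B-M7,3.07,3.52,3.97,8.02,9.01,10,7.03,7.03,7.03
manufacturer,B-M8,7.03,7.48,7.93,3.07,4.01,4.96,4.96,4.96,4.96
manufacturer,B-M9,1.99,1.99,1.99,8.02,9.01,10,2.98,2.98,2.98
manufacturer,B-F1,1.99,1.99,1.99,6.04,6.49,6.94,4.96,4.96,4.96
manufacturer,C-S1,1.99,1.99,1.99,6.04,6.49,6.94,9.01,9.5,10
manufacturer,C-S2,1,1,1,3.07,4.01,4.96,9.01,9.5,10
manufacturer,C-S3,1,1,1,1.99,1.99,1.99,9.01,9.5,10
manufacturer,C-S4,1.99,1.99,1.99,1.99,1.99,1.99,9.01,9.5,10
manufacturer,C-S5,3.07,3.52,3.97,3.07,4.01,4.96,2.98,2.98,2.98
manufacturer,C-S6,3.07,3.52,3.97,3.07,4.01,4.96,2.98,2.98,2.98
manufacturer,C-M1,1,1,1,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,C-M2,5.05,5.5,5.95,3.07,4.01,4.96,2.98,2.98,2.98
manufacturer,C-M3,1,1,1,1,1,1,2.98,2.98,2.98
manufacturer,C-M4,1.99,1.99,1.99,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,C-M5,1,1,1,3.07,4.01,4.96,2.98,2.98,2.98
manufacturer,C-M6,1,1,1,3.07,4.01,4.96,2.98,2.98,2.98
manufacturer,C-M7,3.07,3.52,3.97,6.04,6.49,6.94,2.98,2.98,2.98
manufacturer,C-M8,1,1,1,1,1,1,2.98,2.98,2.98
manufacturer,C-M9,7.03,7.48,7.93,8.02,9.01,10,4.96,4.96,4.96
manufacturer,C-F1,5.05,5.5,5.95,3.07,4.01,4.96,2.98,2.98,2.98
distributor,D-D1,1,1,1,3.07,4.01,4.96,9.01,9.5,10
distributor,D-D2,1.99,1.99,1.99,6.04,6.49,6.94,9.01,9.5,10
distributor,D-D3,1.99,1.99,1.99,6.04,6.49,6.94,9.01,9.5,10
distributor,D-D4,1,1,1,1.99,1.99,1.99,9.01,9.5,10
distributor,D-D5,1,1,1,1.99,1.99,1.99,9.01,9.5,10
distributor,D-F1,1.99,1.99,1.99,6.04,6.49,6.94,9.01,9.5,10
distributor,D-R1,1,1,1,6.04,6.49,6.94,9.01,9.5,10
distributor,D-R2,1,1,1,1,1,1,9.01,9.5,10
distributor,D-R3,1,1,1,6.04,6.49,6.94,9.01,9.5,10
pharmacy,E-C1,3.07,3.52,3.97,6.04,6.49,6.94,9.01,9.5,10
pharmacy,E-C2,5.05,5.5,5.95,6.04,6.49,6.94,9.01,9.5,10
pharmacy,E-C3,5.05,5.5,5.95,6.04,6.49,6.94,9.01,9.5,10
pharmacy,E-C4,1.99,1.99,1.99,3.07,4.01,4.96,9.01,9.5,10
pharmacy,E-C5,1.99,1.99,1.99,3.07,4.01,4.96,9.01,9.5,10
pharmacy,E-R1,1.99,1.99,1.99,3.07,4.01,4.96,9.01,9.5,10
pharmacy,E-R2,1.99,1.99,1.99,3.07,4.01,4.96,9.01,9.5,10
pharmacy,E-R3,5.05,5.5,5.95,6.04,6.49,6.94,9.01,9.5,10
pharmacy,F-C1,3.07,3.52,3.97,6.04,6.49,6.94,9.01,9.5,10
pharmacy,F-C2,3.07,3.52,3.97,6.04,6.49,6.94,9.01,9.5,10
pharmacy,F-C3,3.07,3.52,3.97,3.07,4.01,4.96,9.01,9.5,10
pharmacy,F-C4,1.99,1.99,1.99,3.07,4.01,4.96,1,1,1
pharmacy,F-C5,1.99,1.99,1.99,3.07,4.01,4.96,4.96,4.96,4.96
pharmacy,F-R1,5.05,5.5,5.95,3.07,4.01,4.96,4.96,4.96,4.96
pharmacy,F-R2,1,1,1,3.07,4.01,4.96,9.01,9.5,10
pharmacy,F-R3,3.07,3.52,3.97,6.04,6.49,6.94,9.01,9.5,10
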