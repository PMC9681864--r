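feature,a,n1,c,n2,p_published
low_voltage_moderate,5,156,16,159,0.0268
low_voltage_extreme,0,156,2,159,0.4865
delta_le1,3,156,32,159,0.0000
delta_1_2,53,156,62,159,0.4190
delta_2_3,37,156,49,159,0.1979
delta_3_4,9,156,9,159,0.8406
theta_4_5,36,156,63,159,0.0024
theta_5_6,56,156,40,159,0.0514
theta_6_8,22,156,15,159,0.2663
alpha_le8,28,156,6,159,0.0001
alpha_8_9,19,156,3,159,0.0008
alpha_ge9,17,156,7,159,0.0500
pdr,42,156,0,159,0.0000
grda,3,156,5,159,0.7408
gpds,2,156,14,159,0.0054
lrda,2,156,1,159,0.9868
lpds,1,156,4,159,0.3788
attenuation_brief,0,156,4,159,0.1361
burst_suppression,0,156,1,159,0.9924
seizure,0,156,10,159,0.0042
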