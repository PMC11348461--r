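compound_id,block,X,R1,R2,R3,R4,Y,Z,R5,R6,inhibition_pct,inhibition_sd,hm_predicted,hm_difference_printed,target_log,gep_target_printed,gep_model,gep_residual_printed,is_test
1,1,O,Ph,,,,,,,,68.4,2.9,1.725,-0.110,1.835,1.835,1.964,0.129,TRUE
2,1,CH2,Ph,,,,,,,,90.3,0.9,1.763,-0.192,1.956,1.956,1.824,0.131,FALSE
3,1,CH2,4-F-phenyl,,,,,,,,33.6,1.3,1.770,0.243,1.526,1.526,1.666,0.140,FALSE
4,1,CH2,3-F-phenyl,,,,,,,,56.8,0.7,1.765,0.011,1.754,1.754,1.749,5.461,FALSE
5,1,CH2,4-OMe-phenyl,,,,,,,,16.9,0.1,1.571,0.343,1.228,1.228,1.097,0.130,TRUE
6,1,CH2,3-OMe-phenyl,,,,,,,,47.1,0.6,1.648,-0.025,1.673,1.673,1.910,0.237,FALSE
7,1,CH2,4-Cl-phenyl,,,,,,,,89.0,1.5,1.770,-0.179,1.949,1.949,1.951,1.251,FALSE
8,1,CH2,3-Cl-phenyl,,,,,,,,69.5,3.2,1.762,-0.080,1.842,1.842,1.856,1.352,TRUE
9,1,CH2,4-pyridyl,,,,,,,,41.4,1.0,1.705,0.088,1.617,1.617,1.653,0.036,FALSE
10,1,CH2,3-pyridy,,,,,,,,66.5,1.1,1.713,-0.110,1.823,1.823,1.718,0.105,TRUE
11,1,CH2,3-thienyl,,,,,,,,52.2,1.2,1.766,0.048,1.718,1.718,1.850,0.133,FALSE
12,1,CH2,2-thienyl,,,,,,,,65.4,1.0,1.763,-0.053,1.816,1.816,1.775,4.100,TRUE
13,1,CH2,2-thiazolyl,,,,,,,,86.3,2.2,1.678,-0.258,1.936,1.936,1.813,0.123,FALSE
14,1,CH2,cyclohexyl,,,,,,,,35.4,0.6,1.579,0.030,1.549,1.549,1.679,0.130,FALSE
15,1,CH2,cyclopentyl,,,,,,,,14.0,0.8,1.567,0.421,1.146,1.146,1.203,5.688,FALSE
16,1,CH2,cyclopropyl,,,,,,,,57.4,1.1,1.602,-0.157,1.759,1.759,1.859,0.100,TRUE
b2,2,,,Me,Me,H,,,,,90.3,0.9,1.766,-0.190,1.956,1.956,1.980,2.474,FALSE
17,2,,,Me,H,H,,,,,74.2,6.5,1.889,0.019,1.870,1.870,1.746,0.124,FALSE
18,2,,,F,H,H,,,,,74.0,5.6,1.923,0.054,1.869,1.869,1.971,0.102,TRUE
19,2,,,H,H,H,,,,,55.3,1.8,1.926,0.183,1.743,1.743,1.844,0.102,FALSE
20,2,,,H,H,Me,,,,,69.9,5.4,1.877,0.033,1.845,1.771,1.773,2.267,FALSE
21,2,,,H,H,OMe,,,,,59.0,1.4,1.683,-0.088,1.771,1.849,1.854,4.817,FALSE
22,2,,,H,H,NMe2,,,,,70.6,1.9,1.823,-0.026,1.849,1.812,1.814,2.266,FALSE
23,2,,,H,H,4-morpholinyl,,,,,64.8,5.5,1.726,-0.085,1.812,1.847,1.843,4.358,FALSE
24,2,,,H,H,F,,,,,70.3,5.7,1.915,0.068,1.847,1.857,1.744,0.113,FALSE
25,2,,,H,H,CF3,,,,,72.0,3.7,1.875,0.018,1.857,1.844,1.678,0.166,TRUE
26,2,,,H,H,SO2CH3,,,,,69.9,4.1,1.795,-0.050,1.845,1.844,1.809,3.516,FALSE
b3,3,,,,,,C(=)O,C(=O),H,H,90.3,0.9,2.002,0.046,1.956,1.956,1.815,0.141,FALSE
27,3,,,,,,C(=)O,C(=)O,F,H,83.9,2.4,1.980,0.056,1.924,1.924,1.891,3.248,FALSE
28,3,,,,,,C(=)O,C(=)O,OMe,H,84.4,1.6,1.811,0.116,1.926,1.926,1.868,5.844,FALSE
29,3,,,,,,C(=)O,C(=)O,H,H,89.4,1.3,1.966,0.014,1.951,1.951,1.770,0.181,TRUE
30,3,,,,,,C(=)O,C(=)O,H,H,52.1,1.2,1.890,0.173,1.717,1.717,1.685,3.182,FALSE
31,3,,,,,,C(=)O,C(=)O,H,H,79.3,0.7,1.916,0.016,1.899,1.899,1.908,8.996,FALSE
32,3,,,,,,C(=)O,C(=)O,H,H,82.0,3.7,1.869,-0.045,1.914,1.914,1.908,5.725,FALSE
33,3,,,,,,CH2,C(=)O,H,H,76.5,5.6,1.911,0.028,1.884,1.884,1.799,8.514,FALSE
34,3,,,,,,CH2,C(=)O,H,H,92.9,1.9,1.985,0.017,1.968,1.968,1.954,1.367,FALSE
35,3,,,,,,CH2,C(=)O,H,H,83.3,1.6,1.883,-0.037,1.921,1.921,1.966,4.583,FALSE
36,3,,,,,,CH2,C(=)O,H,H,87.2,0.5,1.833,-0.108,1.941,1.941,1.926,1.487,FALSE
37,3,,,,,,C(=)O,H,H,H,23.1,1.8,1.364,0,1.364,1.363,1.481,0.117,FALSE
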