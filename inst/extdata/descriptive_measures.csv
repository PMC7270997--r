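grid,theta,a,gamma,Mean,Variance,Sk,Kur
theta-varying,0.9,0.9,1,1.84303,2.31852,1.85864,8.59642
theta-varying,1.3,0.9,1,1.15319,0.943471,1.96656,9.27349
theta-varying,1.7,0.9,1,0.803247,0.456862,2.055,10.0151
theta-varying,2.1,0.9,1,0.599871,0.247746,2.09549,10.5227
theta-varying,2.4,0.9,1,0.49818,0.165744,2.09484,10.6905
theta-varying,2.8,0.9,1,0.402164,0.103157,2.06156,10.6462
alpha-varying,0.5,0.7,1,5.75826,36.7515,2.74942,16.2436
alpha-varying,0.5,1.1,1,2.74398,3.16701,1.35913,5.98016
alpha-varying,0.5,1.5,1,2.0152,0.927695,0.818011,4.02501
alpha-varying,0.5,2.5,1,1.4803,0.189286,0.234025,3.06994
alpha-varying,0.5,4.5,1,1.22955,0.0428335,-0.185292,3.11261
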