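"name","D_m2s","representation","nH","nO","charge"
"e_aq",4.9e-09,"point_tracked",0,0,-1
"OH",2.2e-09,"point_tracked",1,1,0
"H",7e-09,"point_tracked",1,0,0
"H2",4.8e-09,"point_tracked",2,0,0
"H2O2",2.3e-09,"point_tracked",2,2,0
"H3O+",9.46e-09,"point_tracked",3,1,1
"OH-",5.27e-09,"point_tracked",1,1,-1
"O-",2e-09,"point_tracked",0,1,-1
"O2",2.4e-09,"continuum",0,2,0
"O2-",1.75e-09,"point_tracked",0,2,-1
"HO2",2.3e-09,"point_tracked",1,2,0
"HO2-",1.4e-09,"point_tracked",1,2,-1
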