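"label","r1","r2","p1","p2","p3","k","type"
"R4","e_aq","OH","OH-",NA,NA,2.95e+10,"second_order"
"r02","e_aq","e_aq","H2","OH-","OH-",5.5e+09,"second_order"
"r03","e_aq","H","H2","OH-",NA,2.65e+10,"second_order"
"r04","e_aq","H3O+","H",NA,NA,2.11e+10,"second_order"
"r05","e_aq","H2O2","OH","OH-",NA,1.41e+10,"second_order"
"R3","OH","OH","H2O2",NA,NA,5.5e+09,"second_order"
"R5","OH","H",NA,NA,NA,1.44e+10,"second_order"
"r08","OH","H2","H",NA,NA,4.2e+07,"second_order"
"R6","OH","H2O2","HO2",NA,NA,2.7e+07,"second_order"
"r10","OH","OH-","O-",NA,NA,1.3e+10,"second_order"
"r13","H","H","H2",NA,NA,7.8e+09,"second_order"
"r14","H","H2O2","OH",NA,NA,9e+07,"second_order"
"r15","H","OH-","e_aq",NA,NA,2.2e+07,"second_order"
"r16","H3O+","OH-",NA,NA,NA,1.43e+11,"second_order"
"r17","H3O+","O2-","HO2",NA,NA,4.78e+10,"second_order"
"r18","H3O+","HO2-","H2O2",NA,NA,4.98e+10,"second_order"
"r19","HO2","HO2","H2O2","O2",NA,830000,"second_order"
"r20","HO2","O2-","HO2-","O2",NA,9.7e+07,"second_order"
"r21","e_aq","HO2","HO2-",NA,NA,2e+10,"second_order"
"r22","e_aq","O2-","HO2-","OH-",NA,1.3e+10,"second_order"
"R1","H","O2","HO2",NA,NA,1.27e+10,"pseudo_first_order"
"R2","e_aq","O2","O2-",NA,NA,1.48e+10,"pseudo_first_order"
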