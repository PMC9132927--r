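# SYNTHETIC stand-in fixture: a 23-component pesticide mixture with mixed modes of action.
# Structures (SMILES) are real pesticides; composition fractions and DRC regression
# parameters are synthetic values generated once under a fixed seed, NOT literature values.
"name","cas","component_type","physical_state","composition_pct","mw","endpoint_type","endpoint_value","endpoint_unit","drc_model","drc_unit","alpha","beta","gamma","delta","smiles"
"Atrazine","1912-24-9","substance","solid",1.87,215.68,"EC50",,,"Weibull","uM",-0.6193,1.905,,,"CCNc1nc(Cl)nc(NC(C)C)n1"
"Simazine","122-34-9","substance","solid",5.5,201.66,"EC50",,,"Logit","uM",-1.9486,3.303,,,"CCNc1nc(Cl)nc(NCC)n1"
"Terbuthylazine","5915-41-3","substance","solid",4.94,229.71,"EC50",,,"Logit","uM",2.0268,3.321,,,"CCNc1nc(Cl)nc(NC(C)(C)C)n1"
"Prometryn","7287-19-6","substance","solid",2.48,241.36,"EC50",,,"Weibull","uM",-0.7122,1.766,,,"CSc1nc(NC(C)C)nc(NC(C)C)n1"
"Ametryn","834-12-8","substance","solid",5.83,227.33,"EC50",,,"Weibull","uM",-1.1477,2.02,,,"CSc1nc(NCC)nc(NC(C)C)n1"
"Diuron","330-54-1","substance","solid",4.5,233.09,"EC50",,,"Logit","uM",-4.5106,3.199,,,"CN(C)C(=O)Nc1ccc(Cl)c(Cl)c1"
"Isoproturon","34123-59-6","substance","solid",7.26,206.28,"EC50",,,"Weibull","uM",-2.5164,2.403,,,"CC(C)c1ccc(NC(=O)N(C)C)cc1"
"Linuron","330-55-2","substance","solid",1.61,249.09,"EC50",,,"Weibull","uM",0.1115,1.839,,,"CON(C)C(=O)Nc1ccc(Cl)c(Cl)c1"
"Monolinuron","1746-81-2","substance","solid",5.59,214.65,"EC50",,,"Logit","uM",0.695,2.737,,,"CON(C)C(=O)Nc1ccc(Cl)cc1"
"Metoxuron","19937-59-8","substance","solid",6.38,228.67,"EC50",,,"Weibull","uM",-0.916,2.466,,,"COc1cc(NC(=O)N(C)C)ccc1Cl"
"Chlorotoluron","15545-48-9","substance","solid",1.16,212.68,"EC50",,,"Logit","uM",-0.0435,1.648,,,"Cc1ccc(NC(=O)N(C)C)cc1Cl"
"Paraquat","4685-14-7","substance","solid",5.89,186.25,"EC50",,,"Weibull","uM",-3.4286,1.874,,,"C[n+]1ccc(-c2cc[n+](C)cc2)cc1"
"2,4-D","94-75-7","substance","solid",3.34,221.04,"EC50",,,"Weibull","uM",0.2361,1.651,,,"OC(=O)COc1ccc(Cl)cc1Cl"
"MCPA","94-74-6","substance","solid",2.88,200.62,"EC50",,,"Logit","uM",-2.2295,2.042,,,"OC(=O)COc1ccc(Cl)cc1C"
"Mecoprop","93-65-2","substance","solid",1.84,214.65,"EC50",,,"Weibull","uM",-1.8346,3.15,,,"OC(=O)C(C)Oc1ccc(Cl)cc1C"
"Dichlorprop","120-36-5","substance","solid",2.56,235.06,"EC50",,,"Weibull","uM",1.3918,3.13,,,"OC(=O)C(C)Oc1ccc(Cl)cc1Cl"
"Pentachlorophenol","87-86-5","substance","solid",13.56,266.34,"EC50",,,"Weibull","uM",0.3041,1.694,,,"Oc1c(Cl)c(Cl)c(Cl)c(Cl)c1Cl"
"2,4-Dinitrophenol","51-28-5","substance","solid",3.05,184.11,"EC50",,,"Weibull","uM",-3.1387,2.744,,,"Oc1ccc([N+](=O)[O-])cc1[N+](=O)[O-]"
"Carbaryl","63-25-2","substance","solid",6.95,201.22,"EC50",,,"Weibull","uM",-5.4046,3.017,,,"CNC(=O)Oc1cccc2ccccc12"
"Carbofuran","1563-66-2","substance","solid",1.67,221.25,"EC50",,,"Weibull","uM",-4.7865,2.766,,,"CNC(=O)Oc1cccc2c1OC(C)(C)C2"
"Aldicarb","116-06-3","substance","solid",3.05,190.27,"EC50",,,"Weibull","uM",-0.1943,1.75,,,"CNC(=O)ON=CC(C)(C)SC"
"Chlorpyrifos","2921-88-2","substance","solid",1.37,350.59,"EC50",,,"Logit","uM",1.1038,3.371,,,"CCOP(=S)(OCC)Oc1nc(Cl)c(Cl)cc1Cl"
"Dimethoate","60-51-5","substance","solid",6.72,229.26,"EC50",,,"Weibull","uM",0.1022,2.298,,,"CNC(=O)CSP(=S)(OC)OC"
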