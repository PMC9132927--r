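# Coating-product (adhesive primer) safety-data-sheet fixture: worst-case (maximum)
# composition percentages and Daphnia magna 48-h EC50 values as published in the
# product SDS literature; no dose-response curves are available, so only the
# Simple-CA model applies.
"name","cas","component_type","physical_state","composition_pct","mw","endpoint_type","endpoint_value","endpoint_unit","drc_model","drc_unit","alpha","beta","gamma","delta","smiles"
"Toluene","108-88-3","substance","liquid",75,92.14,"EC50",11.5,"mg/L",,,,,,,"Cc1ccccc1"
"n-Butanol","71-36-3","substance","liquid",5,74.12,"EC50",1983,"mg/L",,,,,,,"CCCCO"
"2-Butoxyethanol","111-76-2","substance","liquid",5,118.17,"EC50",1000,"mg/L",,,,,,,"CCCCOCCO"
"Ethyl alcohol","64-17-5","substance","liquid",5,46.07,"EC50",9268,"mg/L",,,,,,,"CCO"
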