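# SYNTHETIC stand-in fixture: three perfluorinated carboxylic acids acting as partial
# agonists (PPAR-alpha transactivation study design); Hill-three curves with sub-maximal
# asymptotes so that the decadal effect grid truncates at 60%. Parameter values are
# synthetic, NOT literature values.
"name","cas","component_type","physical_state","composition_pct","mw","endpoint_type","endpoint_value","endpoint_unit","drc_model","drc_unit","alpha","beta","gamma","delta","smiles"
"Perfluorooctanoic acid","335-67-1","substance","solid",33.34,414.07,"EC50",,,"Hill_three","uM",28.5,1.35,0.72,,"OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
"Perfluorononanoic acid","375-95-1","substance","solid",33.33,464.08,"EC50",,,"Hill_three","uM",16,1.2,0.65,,"OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
"Perfluorohexanoic acid","307-24-4","substance","solid",33.33,314.05,"EC50",,,"Hill_three","uM",55,1.05,0.8,,"OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"
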