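tip1,tip2,age,note
A_florea,V_vulgaris,179,bees-wasps split (reported)
M_mesoamerica,V_vulgaris,80,Vespinae-Polistinae split (example value)
A_florea,A_mellifera,30,Apis crown (example value)
A_dorsata,A_mellifera,25,giant vs cavity-nesting honey bees (example value)
A_cerana,A_mellifera,8,cavity-nesting split (example value)
A_florea,A_andreniformis,12,dwarf honey bee split (example value)
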