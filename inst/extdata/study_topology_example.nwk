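(((A_florea,A_andreniformis),(A_dorsata,(A_cerana,A_mellifera))),(M_mesoamerica,(V_vulgaris,((V_flavopilosa,V_maculifrons),V_shidai))));
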