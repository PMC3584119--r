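((H_cunea,L_dispar),(O_lunifer,((T_solitaria,(T_herculeana,T_processionea)),((T_wilkinsoni,(T_pityocampa_ENA,T_pityocampa)),((T_ispartaensis,T_libanotica),(T_bonjeani,T_pinivora))))));
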