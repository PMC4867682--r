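# Published seed-P input characterization of the source seed experiment.
quantity,value,units
five_seed_mass,0.20,g DM
seed_p_conc,3.49,mg P per g DM
reported_seed_p_per_pot,0.71,mg P
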