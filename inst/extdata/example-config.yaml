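# Example run configuration: proofreading relaxation of the 7.9-kb plasmid
seed: 17
plasmid_name: YCp50
plasmid_length_bp: 7900
reference_temperature_C: 25
nk_coefficient: 1100
n_gate_agent: ATP
c_gate: intact
n_molecules: 5000
n_cycles: 300
enzyme_to_dna_ratio: 0.5
gel_noise_sd: 0.002
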