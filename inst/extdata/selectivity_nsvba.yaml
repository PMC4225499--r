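# monovalent substitution panel for the nonselective NsvBa preset
scenario: selectivity
channel: nsvba
ions: [Li, Na, K, Rb, Cs]
seed: 101
noise_sd: 2
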