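# ramp-peak temperature series at neutral and basic pH
scenario: q10
channel: nachbac
temps: [20, 24, 28, 32, 36]
phs: [7.4, 9.4]
seed: 102
noise_sd: 2
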