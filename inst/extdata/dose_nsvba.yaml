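# tamoxifen block of NsvBa peak current
scenario: dose
channel: nsvba
drugs: [tamoxifen]
doses: [3, 10, 30, 100, 300, 1000]
seed: 103
noise_sd: 2
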