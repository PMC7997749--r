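# Admission-proportion bound grid (labels keep the source numbering,
# which has no scenario 4; scenario 3 is the benchmark).
scenarios:
- {label: "1",  mix_upper: [0.9, 0.2, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "2",  mix_upper: [0.8, 0.2, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "3",  mix_upper: [0.7, 0.2, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "5",  mix_upper: [0.7, 0.2, 0.1], mix_lower: [0.6, 0.1, 0.0]}
- {label: "6",  mix_upper: [0.7, 0.2, 0.1], mix_lower: [0.4, 0.1, 0.0]}
- {label: "7",  mix_upper: [0.7, 0.4, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "8",  mix_upper: [0.7, 0.3, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "9",  mix_upper: [0.7, 0.2, 0.2], mix_lower: [0.5, 0.1, 0.0]}
- {label: "10", mix_upper: [0.7, 0.3, 0.1], mix_lower: [0.5, 0.1, 0.05]}
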