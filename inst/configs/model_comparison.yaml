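# Mix-bound settings for the model I vs model II comparison.
mix_scenarios:
- {label: "1", mix_upper: [0.9, 0.2, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "2", mix_upper: [0.7, 0.3, 0.1], mix_lower: [0.5, 0.1, 0.0]}
- {label: "3", mix_upper: [0.7, 0.3, 0.1], mix_lower: [0.5, 0.1, 0.05]}
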