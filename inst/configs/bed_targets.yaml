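# Daily bed-target sweep, 90% to 96% of the 203 available beds.
scenarios:
- {label: "1", bed_target: 183}
- {label: "2", bed_target: 185}
- {label: "3", bed_target: 187}
- {label: "4", bed_target: 189}
- {label: "5", bed_target: 191}
- {label: "6", bed_target: 193}
- {label: "7", bed_target: 195}
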