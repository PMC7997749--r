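# Unit nursing-hours sensitivity grid (one type varied at a time around
# the 1.5 / 1 / 0.5 h base; scenarios 2, 5, 8 are the unmodified benchmark).
scenarios:
- {label: "1", nursing_hours: [1.75, 1.0, 0.5]}
- {label: "2", nursing_hours: [1.5, 1.0, 0.5]}
- {label: "3", nursing_hours: [1.25, 1.0, 0.5]}
- {label: "4", nursing_hours: [1.5, 1.25, 0.5]}
- {label: "5", nursing_hours: [1.5, 1.0, 0.5]}
- {label: "6", nursing_hours: [1.5, 0.75, 0.5]}
- {label: "7", nursing_hours: [1.5, 1.0, 0.75]}
- {label: "8", nursing_hours: [1.5, 1.0, 0.5]}
- {label: "9", nursing_hours: [1.5, 1.0, 0.25]}
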