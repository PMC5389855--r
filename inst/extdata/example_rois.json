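[
  {"subject": "worm_01", "name": "head", "xy": [[8, 10], [24, 8], [28, 16], [22, 24], [10, 22]]},
  {"subject": "worm_02", "name": "head", "xy": [[6, 6], [20, 6], [20, 20], [6, 20]]}
]
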