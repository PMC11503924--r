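{
  "lmc": {"rule": "auto", "levels": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]},
  "lph": {"rule": "auto", "levels": [3, 4, 5, 6, 7, 8, 9, 10]},
  "lt": {"rule": "auto", "levels": [3, 4, 5, 6, 7, 8, 9]},
  "t": {"rule": "explicit", "levels": [2, 3, 4, 5, 6, 7, 8, 9, 10]},
  "rh": {"rule": "auto", "levels": [3, 4, 5, 6, 8, 9, 10]},
  "v": {"rule": "explicit", "levels": [3, 4, 5, 6, 8]}
}
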