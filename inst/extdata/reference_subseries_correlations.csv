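variable,overall,D1,D2,D3,D4,D5,D6,D7,D8,D9,D10
lmc,0.720,0.08,0.08,0.14,0.17,0.29,0.33,0.20,0.33,0.20,0.32
lph,0.547,0.05,0.04,0.11,0.13,0.16,0.25,0.17,0.26,0.16,0.32
lt,-0.398,-0.01,-0.04,-0.09,-0.16,-0.26,-0.15,-0.25,-0.24,-0.09,0.31
t,0.754,-0.03,-0.06,-0.18,-0.24,-0.30,-0.35,-0.26,-0.32,-0.22,-0.32
rh,0.393,0.03,0.05,0.10,0.11,0.11,0.24,-0.01,0.11,0.22,0.30
v,-0.224,0.01,-0.02,-0.16,-0.20,-0.29,-0.18,-0.12,-0.12,0.23,0.30
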