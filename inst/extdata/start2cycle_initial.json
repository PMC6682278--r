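{
  "Trophies": 0,
  "Bug report": 0,
  "Coach": 0.769,
  "Competition": 0.081,
  "Personal": 0,
  "Route": 0,
  "Routes": 0,
  "Team": 0,
  "Track": 0.15,
  "Exit": 0
}
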