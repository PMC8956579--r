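{
  "toggle": {
    "type": "toggle",
    "basal": 0.2,
    "strength": 4,
    "hill": 3
  }
}
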