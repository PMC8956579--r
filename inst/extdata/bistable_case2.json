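{
  "twonode": {
    "type": "twonode",
    "gain1": 6.90932687837631,
    "sat1": 3.95824820967391,
    "rep1": 4.64078774908558,
    "deg1": 1.73918094253168,
    "gain2": 3.81552235223353,
    "sat2": 2.28269627084956,
    "rep2": 1.45229869522154,
    "deg2": 1.88758840318769,
    "vars": ["x", "y"]
  }
}
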