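{
  "twonode": {
    "type": "twonode",
    "gain1": 1.2945368536748,
    "sat1": 3.73834484955296,
    "rep1": 4.64965628925711,
    "deg1": 0.466081888880581,
    "gain2": 9.87516199238598,
    "sat2": 9.08452330389991,
    "rep2": 9.79390146676451,
    "deg2": 1.70472213765606,
    "vars": ["x", "y"]
  }
}
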