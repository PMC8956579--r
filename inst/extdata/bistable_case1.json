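{
  "twonode": {
    "type": "twonode",
    "gain1": 5.33828780753538,
    "sat1": 3.16950157284737,
    "rep1": 8.14757590182126,
    "deg1": 2.92219521244988,
    "gain2": 4.09132091328502,
    "sat2": 0.909183076582849,
    "rep2": 7.98596638021991,
    "deg2": 3.59785249689594,
    "vars": ["x", "y"]
  }
}
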