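{
  "name": "vermis",
  "groups": {
    "whole_vermis": [23, 24, 25, 26, 27, 28, 29, 30, 31, 32]
  }
}
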