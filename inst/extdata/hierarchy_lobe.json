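{
  "name": "lobe",
  "groups": {
    "left_anterior": [1, 2, 3],
    "left_superior_posterior": [4, 5, 6, 7],
    "left_inferior_posterior": [8, 9, 10],
    "left_flocculonodular": [11],
    "right_anterior": [12, 13, 14],
    "right_superior_posterior": [15, 16, 17, 18],
    "right_inferior_posterior": [19, 20, 21],
    "right_flocculonodular": [22]
  }
}
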