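{
  "name": "lobule",
  "groups": {
    "Left_I_III": [1], "Left_IV": [2], "Left_V": [3], "Left_VI": [4],
    "Left_Crus_I": [5], "Left_Crus_II": [6], "Left_VIIB": [7],
    "Left_VIIIA": [8], "Left_VIIIB": [9], "Left_IX": [10], "Left_X": [11],
    "Right_I_III": [12], "Right_IV": [13], "Right_V": [14], "Right_VI": [15],
    "Right_Crus_I": [16], "Right_Crus_II": [17], "Right_VIIB": [18],
    "Right_VIIIA": [19], "Right_VIIIB": [20], "Right_IX": [21],
    "Right_X": [22],
    "Vermis_I_II": [23], "Vermis_III": [24], "Vermis_IV_V": [25],
    "Vermis_VI": [26], "Vermis_VIIA": [27], "Vermis_VIIB": [28],
    "Vermis_VIIIA": [29], "Vermis_VIIIB": [30], "Vermis_IX": [31],
    "Vermis_X": [32]
  }
}
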