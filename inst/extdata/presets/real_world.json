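{
  "n": 646,
  "p_male": 0.5340557,
  "p_spinal": 0.7089783,
  "age": [62.2, 12.1, 26.3, 92.2],
  "symptom_duration": [22.1, 21.6, 0.5, 228.5],
  "weight": [70.4, 13.2, 40, 140],
  "alsfrs": [28.6, 7.4, 3.5, 40],
  "target_survival": 0.67
}
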