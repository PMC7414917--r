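{
  "n": 172,
  "p_male": 0.6860465,
  "p_spinal": 0.75,
  "age": [55.6, 12.0, 26.3, 77.9],
  "symptom_duration": [24.7, 11.9, 5, 58],
  "weight": [70.1, 13.8, 45, 112],
  "alsfrs": [27.5, 6.4, 10, 39],
  "target_survival": 0.72
}
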