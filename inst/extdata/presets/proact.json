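{
  "n": 3971,
  "p_male": 0.6257869,
  "p_spinal": 0.7849408,
  "age": [56.2, 11.3, 18, 81],
  "symptom_duration": [20.8, 12.7, 0.5, 140.4],
  "weight": [74.8, 15.8, 30, 148.6],
  "alsfrs": [30.1, 5.7, 7, 40],
  "target_survival": 0.76
}
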