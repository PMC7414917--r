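{
  "n": 5220,
  "p_male": 0.6178161,
  "p_spinal": 0.7758621,
  "age": [57.0, 11.6, 18, 92.2],
  "symptom_duration": [20.7, 13.9, 0.5, 228.5],
  "weight": [73.8, 15.3, 30, 148.6],
  "alsfrs": [30, 5.9, 3.5, 40],
  "target_survival": 0.75
}
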