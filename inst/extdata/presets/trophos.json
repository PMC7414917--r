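{
  "n": 431,
  "p_male": 0.6426914,
  "p_spinal": 0.8027842,
  "age": [56.7, 11.1, 26, 79],
  "symptom_duration": [16.4, 8.0, 5, 38],
  "weight": [71.5, 12.7, 41, 130],
  "alsfrs": [32.5, 4.1, 16, 40],
  "target_survival": 0.84
}
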