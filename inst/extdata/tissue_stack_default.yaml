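# Default five-layer anterior neck model, ordered lumen -> skin.
# thickness in mm; mu_a, mu_s in 1/cm.
- name: mucosa
  thickness_mm: 1.5
  mu_a_per_cm: 0.70
  mu_s_per_cm: 173.0
  g: 0.95
  n: 1.40
- name: cartilage
  thickness_mm: 1.0
  mu_a_per_cm: 1.00
  mu_s_per_cm: 100.0
  g: 0.92
  n: 1.45
- name: adipose
  thickness_mm: 6.5
  mu_a_per_cm: 0.22
  mu_s_per_cm: 119.0
  g: 0.79
  n: 1.40
- name: muscle
  thickness_mm: 6.5
  mu_a_per_cm: 0.35
  mu_s_per_cm: 83.0
  g: 0.90
  n: 1.40
- name: skin
  thickness_mm: 0.5
  mu_a_per_cm: 1.80
  mu_s_per_cm: 408.0
  g: 0.95
  n: 1.36
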