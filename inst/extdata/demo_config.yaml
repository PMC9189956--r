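# Demonstration pipeline configuration: a small synthetic register with all
# six relative classes and every analysis stage enabled.
seed: 1
n_families: 5000
birth_window: [1960, 2010]
late_window: [1980, 2010]
min_survival_age: 10
min_cases: 20
exposure: adhd
outcome: anyAD
relations: [mother, father, full_sibling, aunt, uncle, cousin]
contrasts: [mother_vs_father, aunt_vs_uncle, maternal_side_vs_paternal_side]
spline_knots: 5
n_boot: 200
quantgen:
  n_starts: 2
  run: true
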