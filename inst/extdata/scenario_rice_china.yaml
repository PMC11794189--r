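# Default economic-risk parameterization: rice production in the
# suitable range of an invasive rice pest in China. PERT (min, mode,
# max) triples; `percent: true` entries are divided by 100 at load.
# C is a per-area prevention cost in $/hm^2: F2 = S * I * C is then a
# dollar amount.
inputs:
  Q:   # rice yield in suitable habitats, t
    min: 192633999.68
    mode: 194501221
    max: 196083353.35
  I:   # damage rate
    min: 10
    mode: 30
    max: 50
    percent: true
  R:   # yield loss rate
    min: 15.9
    mode: 51.35
    max: 86.8
    percent: true
  Pa:  # rice market price, $/t
    min: 374.12
    mode: 402.32
    max: 544.83
  S:   # planted area in suitable habitats, hm^2
    min: 27363597.06
    mode: 27683966.83
    max: 27966379.44
  C:   # unit prevention cost, $/hm^2
    min: 5.87
    mode: 39.85
    max: 110.64
  W:   # unit yield, t/hm^2
    min: 6.99
    mode: 7.03
    max: 7.07
  M:   # control effect
    min: 72.44
    mode: 78.35
    max: 84.25
    percent: true
D: 2
n_iterations: 100000
seed: 1
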