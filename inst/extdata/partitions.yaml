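# Default fuzzy-system configuration: triangular membership partitions for
# the three candidate inputs and the blood-state output.
partitions:
  - variable: hgb
    universe: [7, 16.6]
    centers: [8, 10.25, 14.1, 16.6]
    labels: ["Very Low", "Low", "Normal", "High"]
  - variable: pao2
    universe: [40, 80]
    centers: [30, 47.5, 65.75, 90]
    labels: ["Normal", "Mild Hypoxemia", "Moderate Hypoxemia", "Severe Hypoxemia"]
  - variable: ph
    universe: [6.3, 7.8]
    centers: [7.35, 7.4, 7.45]
    labels: ["Acidosis", "Normal", "Alkalosis"]
  - variable: state
    universe: [0, 1]
    centers: [0.25, 0.75]
    labels: ["Low", "Normal"]
output: state
inputs: [hgb, pao2]
normalize: true
alarm_threshold: 0.5
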