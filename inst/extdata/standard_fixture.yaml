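# Standard synthetic fixture: 3 Gaussian cell populations over 4
# fluorescence channels, observed through a known spillover matrix.
n_events: 10000
seed: 42
channels: [FL1-A, FL2-A, FL3-A, FL4-A]
markers: [CD3, CD4, CD8, CD19]
components:
  - weight: 0.5
    mean: [20000, 20000, 5000, 5000]
    cov:
      - [9000000, 2700000, 0, 0]
      - [2700000, 9000000, 0, 0]
      - [0, 0, 9000000, 0]
      - [0, 0, 0, 9000000]
  - weight: 0.3
    mean: [60000, 5000, 40000, 8000]
    cov:
      - [9000000, -1800000, 0, 0]
      - [-1800000, 9000000, 0, 0]
      - [0, 0, 9000000, 0]
      - [0, 0, 0, 9000000]
  - weight: 0.2
    mean: [5000, 60000, 20000, 45000]
    cov:
      - [9000000, 900000, 0, 0]
      - [900000, 9000000, 0, 0]
      - [0, 0, 9000000, 0]
      - [0, 0, 0, 9000000]
spillover:
  - [1, 0.12, 0, 0]
  - [0.08, 1, 0.10, 0]
  - [0, 0.05, 1, 0.15]
  - [0, 0, 0.07, 1]
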