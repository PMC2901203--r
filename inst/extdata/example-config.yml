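# Example run configuration for the bgfmap command-line driver.
# All sections are optional; unknown keys are rejected.
seed: 20260922
demography:
  phase1Size: 500
  phase1Generations: 1000
  phase2Size: 100
  phase2Generations: 50
  mutationRate: 2.5e-5
panel:
  markerSpacingCM: 0.1      # 0.1, 0.05 or 0.02
study:
  sampleSize: 500
  qtlVarianceFraction: 0.05 # 0 simulates a null (no-QTL) dataset
method:
  k: 1                      # markers per haplotype (1 or 2)
  sigma2Mu: 1
  nuE: 4
  s2E: 0.5
  sigma2X: 4
  nIterations: 20000
  burnIn: 5000
  thinning: 5
experiment:
  methods: [BGF1, LSR1]
  nNullReps: 150
  nPowerReps: 150
  level: 0.10
  reuseHistory: false
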