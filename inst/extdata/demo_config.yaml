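# Demo configuration: a small, fully deterministic end-to-end run on
# synthetic data (lattice source space, planted effects and one lagged
# coupling).  Sizes are reduced so the demo completes quickly on one CPU.
outdir: "demo_out"
seeds:
  simulate: 101
  regression: 202
  decoding: 303
  connectivity: 404
space:
  nrow: 8
  ncol: 8
  analysisMask: "language"
  regions:
    language: [1, 8, 1, 6]   # rowMin, rowMax, colMin, colMax
    roiA: [1, 4, 1, 3]
    roiB: [5, 8, 1, 3]
simulate:
  nSubjects: 8
  trialsPerCondition: 20
  sampleRateHz: 250
  noise:
    sensorSd: 1.0
    spatialCorrLength: 2
    subjectSd: 0.1
    temporalSmoothingMs: 20
  effects:
    - predictor: "interaction"
      region: "roiA"
      windowMs: [640, 760]
      amplitude: 2.0
    - predictor: "composition"
      region: "roiB"
      windowMs: [690, 880]
      amplitude: -1.0
    - predictor: "condition-patterns"
      region: "roiA"
      windowMs: [600, 1200]
      amplitude: 1.5
      form: "multivariate-pattern"
      patternSeed: 11
  couplings:
    - sourceRegion: "roiA"
      targetRegion: "roiB"
      lagMs: 100
      gain: 1.2
      windowMs: [600, 1200]
  freqEffect:
    region: "language"
    slope1: -0.5
    slope2: -0.5
preprocess:
  decimate: 5
regression:
  windowMs: [0, 1200]
  predictors: ["interaction", "composition"]
  nPerm: 100
  alpha: 0.05
decoding:
  windowMs: [600, 1200]
  nSourcesPerLight: 20
  nTimepointsPerLight: 5
  sourceStride: 6
  timeStride: 5
  nPseudo: 10
  nReps: 8
  nPerm: 100
connectivity:
  roiA: "roiA"
  roiB: "roiB"
  tWindowMs: [600, 1200]
  dtMaxMs: 300
  dtStepMs: 10
  nPseudo: 10
  nPerm: 100
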