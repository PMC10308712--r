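# ssfuse run configuration template.
# Every field is optional; omitted fields fall back to package defaults.
#
# Published hyper-parameter search grids (selection made on the GBM cohort
# and reused for the others):
#   margin:        [1, 2, 3, 4, 5]          -> selected 2.0
#   learning rate: [0.0001, 0.0003, 0.0005, 0.0007, 0.0009, 0.001]
#                                           -> selected 0.0003
#   batch size:    [20, 30, 40, 50]         -> selected 30

# mapping:              # omit to derive from the data dimensions
#   inputDims: [12042, 534, 1305]
#   hiddenDims: [4096, 534, 768]
#   outputDim: 534      # default: smallest modality dimension

net:
  hiddenSizes: [256, 128] # shared/specific branch hidden widths
  embedSize: 32           # embedding width (fused dim = (K+1)*embedSize)
  classifierHidden: 32

weights:
  wCE: 1.0
  wDiff: 0.1   # layer-wise orthogonality
  wDiss: 0.1   # layer-wise cross-modality Euclidean distance
  wCon: 0.1    # contrastive
  margin: 2.0
  # constraintLayers: "last"   # uncomment for the ICLL ablation

train:
  learningRate: 0.0003
  batchSize: 30
  maxEpochs: 300
  patience: 20
  seed: 1
  threshold: 0.5
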