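# Example end-to-end run: simulate the desk-scale dataset and train the
# 2-D CNN on 16 x 150 spectral matrices. Fields omitted here keep the
# defaults of default_run_config().
simulate: true
part: underground
h: 150
model: cnn2d
schedule:
  learning_rates: [0.1, 0.05, 0.01, 0.005]
  thresholds: [0.6, 0.75, 0.92, 0.96]
  batch_size: 16
seeds:
  simulation: 1
  split: 1
  selection: 1
  training: 1
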