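# Desk-scale demo configuration for the retquant pipeline.
# Every stage runs in a couple of minutes on one CPU; re-running with the
# same seed reproduces all CSV outputs bit-exactly.
seed: 1
out_dir: retquant_demo
profile:
  image_height: 128
  image_width: 256
synth:
  n_train: 4
  n_test: 2
  speckle_sigma: 0.0
detector:
  epochs: 2
  channels: [4, 8, 16, 32]
segmenter:
  epochs: 2
  channels: [4, 8, 16]
evaluate:
  n_boot: 100
predict:
  n_eyes: 30
  n_trees: 150
  cv_folds: 5
  variant: six_metric
  horizon: month3
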