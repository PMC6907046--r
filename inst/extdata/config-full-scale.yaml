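# Full-scale training recipe for 512 x 512 ROIs (GPU-era settings; on a
# laptop CPU prefer the desk-scale defaults baked into trainConfig()).
train:
  epochs: 500
  batch: 20
  lr: 1.0e-4
  seed: 7
  window: 17
  stride: 8
  levels: 32
  distances: "1,2"
segment:
  max-iter: 5
  conv-dsc: 0.999
simulate:
  size: 512
  sigma: 10
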