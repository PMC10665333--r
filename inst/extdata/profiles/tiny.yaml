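# Desk-scale profile for experiments on synthetic clips: same layout,
# 1/1/2/1 residual groups, alpha = 2, beta = 1/2.
x3d:
  stage_groups: [1, 1, 2, 1]
  stage_channels: [8, 12, 16, 24]
  t_frames: 4
  spatial_strides: [1, 2, 2, 2]
  attention: true
  conv_style: depthwise_separable
  stem_channels: 8
  stem_kernel: [3, 3, 3]
  stem_stride: [1, 2, 2]
fast:
  stage_groups: [1, 1, 2, 1]
  stage_channels: [4, 6, 8, 12]
  t_frames: 8
  spatial_strides: [1, 2, 2, 2]
  attention: false
  conv_style: r2plus1d
  stem_channels: 4
  stem_kernel: [3, 3, 3]
  stem_stride: [1, 2, 2]
lateral:
  kernel: [5, 1, 1]
  pad: [2, 0, 0]
  se_ratio: 16
num_classes: 4
predictor_hidden: 64
dropout: 0.5
action_r: 16
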