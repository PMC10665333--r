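# Full two-pathway profile: X3D pathway 3/5/11/7 residual groups,
# fast pathway at alpha = 4 frame rate with beta = 1/8 channel ratio.
x3d:
  stage_groups: [3, 5, 11, 7]
  stage_channels: [24, 48, 96, 192]
  t_frames: 8
  spatial_strides: [1, 2, 2, 2]
  attention: true
  conv_style: depthwise_separable
  stem_channels: 24
  stem_kernel: [3, 3, 3]
  stem_stride: [1, 2, 2]
fast:
  stage_groups: [3, 5, 11, 7]
  stage_channels: [3, 6, 12, 24]
  t_frames: 32
  spatial_strides: [1, 2, 2, 2]
  attention: false
  conv_style: r2plus1d
  stem_channels: 3
  stem_kernel: [3, 3, 3]
  stem_stride: [1, 2, 2]
lateral:
  kernel: [5, 1, 1]
  pad: [2, 0, 0]
  se_ratio: 16
num_classes: 4
predictor_hidden: 256
dropout: 0.5
action_r: 16
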