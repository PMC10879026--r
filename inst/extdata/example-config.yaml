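# Example configuration for the rbcdetect command line.
# Each block feeds the constructor of the same name; omitted keys keep
# their package defaults.

scene:
  image_height: 256
  image_width: 256
  n_cells: 30
  radius_range: [8, 14]
  eccentricity_range: [0.0, 0.4]
  overlap_fraction: 0.2
  cell_intensity: 0.35
  background_intensity: 0.85
  gradient_strength: 0.05
  noise_sigma: 0.02
  speckle_strength: 0.05

filter:
  sigma_d: 1.5
  sigma_r: 0.1
  n_iterations: 3

augment:
  rescale: 1          # use 0.00392157 (1/255) for raw 8-bit input
  rotation_range: 0.2
  width_shift: 0.2
  height_shift: 0.1
  shear_range: 0.1
  zoom_range: 0.5
  horizontal_flip: yes
  fill_mode: nearest

detector:
  stride: 8
  scales: [12, 20, 32]
  ratios: [1.0]
  epochs: 12
  lr: 0.001

postprocess:
  enable: yes
  rgi_threshold: 0.0
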