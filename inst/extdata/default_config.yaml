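diameters:
- 1.5875
- 3.175
- 4.7625
- 6.35
- 7.9375
- 9.525
- 12.7
- 15.875
- 19.05
- 22.225
- 25.4
n_replicates: 5.0
container:
- 152.0
- 152.0
- 400.0
background_hu: 37.6
sphere_hu: 118.2
fov_cm:
- 20.0
- 30.0
- 40.0
kernels:
- standard
- lung
- bone
thicknesses:
- 0.625
- 1.25
- 2.5
- 5.0
native_thickness: 0.625
matrix_size: 512.0
supersample: 8.0
threshold: 93.0
min_volume: 1.6758294
min_neighbors: 3.0
connectivity: full-26
calibrate: no
calibration_thresholds:
- 90.0
- 100.0
- 110.0
calibration_cases:
- fov: 20.0
  kernel: standard
  slice_thickness: 0.625
- fov: 40.0
  kernel: bone
  slice_thickness: 5.0
- fov: 30.0
  kernel: lung
  slice_thickness: 2.5
kernel_models:
- name: standard
  psf_sigma_xy: 0.8
  noise_sigma: 4.0
- name: lung
  psf_sigma_xy: 0.3
  noise_sigma: 8.0
- name: bone
  psf_sigma_xy: 0.5
  noise_sigma: 10.0
seed: 2010
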