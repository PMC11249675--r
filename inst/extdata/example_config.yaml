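# Example sofisect run configuration: a small TF z-scan of a flat
# quantum-dot layer. All lengths carry explicit unit suffixes.
seed: 7
optics:
  numerical_aperture: 1.4
  refractive_index: 1.515
  excitation_wavelength_nm: 1030
  emission_wavelength_nm: 705
  tube_focal_length_mm: 400
  magnification: 100            # objective focal length = 200 mm / 100 = 2 mm
  beam_diameter_at_grating_mm: 8
  pixel_size_sample_nm: 46
psf:
  lateral_fwhm_nm: 274          # measured intensity-image PSF
  axial_fwhm_nm: 680            # detection axial FWHM (explicit, no hidden default)
sectioning:
  a_per_um2: 0.666              # TF sectioning parameter; FWHM = 2/sqrt(a) = 2.45 um
  z0_um: 0
excitation:
  mode: tf                      # tf | widefield
kinetics:
  p_on_to_off: 0.2
  p_off_to_on: 0.2              # stationary ON fraction 0.5, ~5-frame dwell
camera:
  read_noise_sd_counts: 0.3
  offset_counts: 5
  max_count: 200                # photon-number-resolving dynamic range
  quantize: true
  shot_noise: true
plan:
  n_frames: 300
  exposure_ms: 1
  frame_rows: 64
  frame_cols: 64
  pixel_size_nm: 46
  z_positions_um: {from: -3.0, to: 3.0, by: 0.3}   # 21 planes at 300 nm
sample:
  type: flat_layer              # flat_layer | grid | explicit
  n_emitters: 150
  field_um: 2.9
  z_um: 0
  brightness: 2500
  bleach_rate_per_frame: 0
analysis:
  order: 2
  lag: 0
  n_regions: 8
  fit: gaussian
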