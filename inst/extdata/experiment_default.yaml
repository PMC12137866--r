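phantom_preset: cell
nx: 256
ny: 256
phantom_seed: 1
phantom_overrides: []
schedules:
  dwell_ns:
  - 100.0
  - 500.0
  - 1000.0
  reps:
  - 100
  - 20
  - 10
strategies:
- raster_li
- raster_fi
- interleaved_fi
skip: 2
flyback_delay_ns: 70000.0
params:
  q0_electrons: ~
  current_pA: 6.3
  probe_fwhm_nm: 2.0
  D_px2_per_ns: 5.0e-06
  alpha: 0.5
  sigma_local_px: 8.0
  noise_std: 150.0
  detector_gain: 12000.0
  detector_offset: 2000.0
  batch_visits: ~
  discharge_enabled: no
  discharge_threshold: 50.0
  discharge_gain: 8000.0
  drift_step_px: 0.0
  burnspot_enabled: no
seeds:
- 1
- 2
- 3
- 4
- 5
crop_flyback_px: 0
center_crop_px: ~
align: yes
output_dir: ~
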