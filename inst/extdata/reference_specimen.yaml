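schema: glenosim-specimen-1
name: reference
seed: .na.integer
insertion_mm:
  MD:
  - 0.0
  - -60.0
  - -10.0
  AD:
  - 15.0
  - -50.0
  - -2.0
  PD:
  - -15.0
  - -50.0
  - -2.0
  ISP_TM:
  - 25.0
  - -6.0
  - 0.0
  SSC:
  - -25.0
  - -6.0
  - 0.0
  SSP:
  - 0.0
  - 18.0
  - -20.0
guide_mm:
  MD:
  - 0.0
  - 36.0
  - -34.0
  AD:
  - 50.0
  - 25.0
  - -5.0
  PD:
  - -48.0
  - 24.0
  - -8.0
  ISP_TM:
  - 30.0
  - -10.0
  - 85.0
  SSC:
  - -30.0
  - -10.0
  - 85.0
  SSP:
  - 0.0
  - 26.0
  - 46.0
pcsa_cm2:
  MD: 9.640000000000001
  AD: 4.7
  PD: 5.44
  ISP_TM: 12.300000000000001
  SSC: 15.6
  SSP: 5.26
mvc_n:
  MD: 241.0
  AD: 118.0
  PD: 136.0
  ISP_TM: 308.0
  SSC: 390.0
  SSP: 132.0
loading_ratio:
  MD: 1.0
  AD: 0.43
  PD: 0.17
  ISP_TM: 0.78
  SSC: 0.22
ssp_table:
  abduction_deg:
  - 10.0
  - 30.0
  - 60.0
  ratio:
  - 0.99
  - 0.52
  - 0.3
couple_cap_adpd_n: 254.0
pretension_n: 12.0
pretension_floor_n: 10.0
mass_kg:
  humerus: 2.0
  forearm: 3.0
mass_pos_mm:
  humerus:
  - 0.0
  - -90.0
  - 0.0
  forearm:
  - 0.0
  - -150.0
  - 0.0
inertia_kgm2:
- 0.09
- 0.09
- 0.004
k_passive_nm_rad:
- 3.0
- 0.8
- 1.2
c_passive_nms_rad:
- 1.2
- 1.0
- 0.5
rest_deg:
- 0.0
- 0.0
- 0.0
k_trans_n_mm:
- 12.0
- 18.0
- 35.0
head_center_offset_mm:
- 3.0
- 4.0
- -4.0
translation_ref_pose_deg:
- 10.0
- 0.0
- 0.0
inclination_deg: 10.0
gravity_ms2:
- 0.0
- -9.66096405704976
- -1.703488622912587
dislocation_limit_mm: 22.0
speed_limit_deg_s: 120.0
noise_sd:
  angle_deg: 0.1
  force_n: 0.5
  translation_mm: 0.1
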