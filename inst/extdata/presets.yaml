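# Generator presets pinned to the reported group means.
# frac_* are ground-truth area fractions of total xylem area (PA / 100);
# radial targets are the percent of covered xylem area at which the
# cumulative area of the placed component reaches 95%.
ctr:
  group: CTR
  frac_vessels_embolized: 0.0018
  frac_fibers_airfilled: 0.0
  radial_target_vessels: uniform
  radial_target_fibers: uniform
fdd:
  group: FDD
  frac_vessels_embolized: 0.1086
  frac_fibers_airfilled: 0.0198
  radial_target_vessels: 78.8
  radial_target_fibers: 55.1
sdd:
  group: SDD
  frac_vessels_embolized: 0.0997
  frac_fibers_airfilled: 0.0326
  radial_target_vessels: 72.8
  radial_target_fibers: 55.1
r_fdd:
  group: R_FDD
  frac_vessels_embolized: 0.0543
  frac_fibers_airfilled: 0.003
  radial_target_vessels: 74.6
  radial_target_fibers: 55.1
r_sdd:
  group: R_SDD
  frac_vessels_embolized: 0.0748
  frac_fibers_airfilled: 0.0326
  radial_target_vessels: 59.6
  radial_target_fibers: 55.1
pooled:
  group: POOLED
  frac_vessels_embolized: 0.104
  frac_fibers_airfilled: 0.026
  radial_target_vessels: 68.0
  radial_target_fibers: 55.1
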