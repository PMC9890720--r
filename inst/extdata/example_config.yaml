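# Example pipeline configuration for a synthetic TMA cohort run.
# All densities in cells/mm^2, lengths in micrometres.
out_dir: immunotopo_out
seed: 1
cohort:
  n_cases: 12
  markers: [CD3, CD8]
  marker_medians: {CD3: 582.3, CD8: 291.6}
  core:
    core_diameter: 800
    pixel_size: 2
stains:
  haematoxylin: [0.650, 0.704, 0.286]
  dab: [0.269, 0.568, 0.778]
  background: [255, 255, 255]
detection:
  default:
    smoothing_sigma: 1.5
    background_radius: 8
    detection_threshold: 0.1
    min_area: 10
    max_area: 400
    dab_positive_threshold: 0.2
    watershed_split: true
classifier:
  n_trees: 100
  max_depth: 16
  n_train_cases: 2
threshold_derivation: cohort_median_overall
combos:
  CD3/CD8: [CD3, CD8]
combo_rule: and
cps_cutoff: 10
log_level: info
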