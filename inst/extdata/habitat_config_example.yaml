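# Example habitat configuration.
#
# Zone thresholds are the baleen-corrected POM isoscape defaults. The prey
# boxes are SYNTHETIC placeholders illustrating the expected schema; replace
# them with ranges digitised from the primary literature before drawing any
# ecological conclusion, and supply the carbon krill-to-baleen factor your
# prey sources require (no default is shipped for it).
zones:
  southern_ocean_max: -21.32
  subantarctic_min: -20.22
  seasonal_variation: 1.1
factors:
  d13C_pom_to_skin: 1.7
  d13C_skin_to_baleen: 0.98
  d15N_krill_to_baleen: 2.77
  d15N_krill_to_baleen_sd: 0.22
  d13C_krill_to_baleen: 1.28
prey_boxes: prey_boxes_synthetic.csv
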