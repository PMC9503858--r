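# Example study configuration: PRRT with 177Lu-DOTA-TATE.
# The S values referenced here are the package's synthetic illustration
# table (inst/extdata/sfactors_synthetic.csv), NOT an OpenDose export:
# substitute a real export (same CSV layout) for clinical use, and set
# kappa to the marrow-to-low concentration ratio of your protocol.
kinetics:
  preset: lu177_dotatate
segmentation:
  selection: plateau      # or nnuf_cutoff
  nnuf_cutoff: 0.5
  connectivity: 8
  body_fraction: 0.01
  n_steps: 100
dosimetry:
  kappa: 1.0
  delta_keV: 147
  phi: 1.0
  phi_SL: 1.0
  self_dose_mode: concentration
  S_override:
    high: 2.6e-4
    low: 2.0e-4
lesions:
  skeletal_focus_labels: []
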