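# Example study configuration: every key is optional and overrides the
# package defaults. Unknown keys are rejected.
medium:
  temperature: 310.15     # K
  viscosity: 8.12e-4      # Pa s
  rho_medium: 1.00        # g/cm^3
well:
  liquid_height: 5.5      # mm
  volume: 200             # uL
  cells_per_well: 70000
  travel_length: 1.0      # mm
window: [450, 650]        # nm
rho_shell:
  water: 1.064            # g/cm^3
  ccm: 1.125
rho_core: 19.3            # g/cm^3 (gold)
ratio_band: 1.25
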