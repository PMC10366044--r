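# Default configuration of the three-stage VEGFR2 relocation simulation.
# Densities in molecules/um^2, lengths in um, times in s, energies in J/mol.
r0: 10.0
n_nodes: 200
N_receptors: 24000
model: base            # base | split
immobile_frac: 0.23    # split model only (FRAP estimate)
chemistry:
  dG0: -32949.0        # standard Gibbs free energy of binding
  T: 310.15            # absolute temperature
  cLmax: 16000         # ligand saturation limit
  cLav: 90             # maximum available-ligand density at contact
  ell_chem: 0.2        # chemical length scale
  D_R: 0.198           # receptor diffusivity
stages:
  t_attach: 300
  t_transloc: 600
  t_end: 7200
  dt_stage: [0.5, 0.1, 0.05]
  substeps: 100
contact:
  a_attach: 3.35       # contact radius at end of attachment (diameter 6.7)
  a_final: 19.8        # contact radius at end of translocation (diameter 39.6)
output_every: 10
store_fields: true
mass: lumped
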