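# Reference configuration: open EGFR conformation, reference membrane.
# Units: nm, kBT0.
params:
  B: 10.0        # monolayer bending modulus (kBT0)
  K: 10.0        # monolayer tilt modulus (kBT0/nm^2)
  sigma: 0.01    # monolayer lateral tension (kBT0/nm^2)
  h_r: 1.8       # ordered monolayer thickness (nm)
  h_s: 1.3       # disordered monolayer thickness (nm)
  a_qm: 0.5      # area per quasimolecule (nm^2)
  Delta: 0.01    # subsaturation
  kT: 1.0        # thermal energy (kBT0)
geometry:
  conformation: open
  n1: 0.5
  n2: -0.2
scan:
  grid_step: 0.1
  L_min: 2.0
  L_max: 14.0
  dL: 0.5
  L_u_fixed: 7.0
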