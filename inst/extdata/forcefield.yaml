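# Nonbonded parameters: TIP3P water plus CHARMM-compatible monovalent ions
# and a neutral aromatic-type carbon for the frozen sheet. Literature values,
# versioned with the package.
version: 1
units:
  epsilon: kcal/mol
  rmin_half: angstrom
  mass: g/mol
  charge: e
water_geometry:
  r_OH: 0.9572
  angle_HOH: 104.52
switching:
  r_on: 10.0
  r_off: 12.0
electrostatics:
  eps_rf: .inf    # conducting-boundary reaction field
species:
  OW: {mass: 15.9994,  charge: -0.834, epsilon: 0.1521, rmin_half: 1.7682}
  HW: {mass: 1.008,    charge:  0.417, epsilon: 0.046,  rmin_half: 0.2245}
  NA: {mass: 22.98977, charge:  1.0,   epsilon: 0.0469, rmin_half: 1.36375}
  K:  {mass: 39.0983,  charge:  1.0,   epsilon: 0.0870, rmin_half: 1.76375}
  CL: {mass: 35.453,   charge: -1.0,   epsilon: 0.150,  rmin_half: 2.27}
  C:  {mass: 12.011,   charge:  0.0,   epsilon: 0.07,   rmin_half: 1.9924}
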