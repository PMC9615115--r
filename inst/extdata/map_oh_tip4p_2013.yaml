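# Electric-field spectroscopic map for the water O-H stretch.
#
# Transcribed from the TIP4P-family O-H map of Gruenbaum, Tainter, Shi,
# Ni & Skinner, J. Chem. Theory Comput. 9, 3109-3117 (2013).  The map
# links the electric field E (atomic units) at the H atom, projected on
# the O->H unit vector, to the 0->1 frequency, position matrix element
# and transition-dipole derivative of that O-H bond.  Polynomials are
# listed lowest power first.
#
# Units: frequencies cm-1, fields a.u., positions Angstrom.
schema_version: 1
source: "Gruenbaum et al. (2013) JCTC 9, 3109; O-H stretch map for 4-site water"
freq_poly: [3760.2, -3541.7, -152677.0]        # w10(E), cm-1
position_poly: [0.19285, -1.7261e-5]           # x10(w10), Angstrom
dipole_poly: [0.1646, 11.39, 63.41]            # mu'(E), arbitrary units
coupling:                                      # intramolecular w12, cm-1:
  mixed_poly: [-1361.0, 27165.0]               #  (c0 + c1*(E1+E2)) * x1 * x2
  offset: -1.887                               #  + offset
polarizability_ratio: 0.179                    # transverse/parallel alpha'
alpha_parallel_scale: 1.0                      # overall alpha' scale (arbitrary)
field_cutoff: 7.831                            # Angstrom, charge summation cutoff
isotope_mass_O: [15.9949146196, 17.9991596129] # 16O, 18O (amu)
mass_H: 1.00782503207
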