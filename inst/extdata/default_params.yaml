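# Default physical parameters and per-term weights.
# All energies in kcal/mol, distances in Angstrom, angles in degrees unless noted.
physical:
  temperature: 298.0        # K
  ionic_strength: 0.05      # M
  dielectric: 80.0
  coulomb_constant: 332.0   # kcal * A / (mol * e^2)
weights:
  hbond: 1.0
  electrostatics: 1.0
  disulfide: 1.0
  solvation_polar: 1.0
  solvation_hydrophobic: 1.0
  vdw: 1.0
  clash: 1.0
  entropy_backbone_omega: 1.0     # w1 on -ln KDE_o(omega)
  entropy_backbone_phipsi: 1.0    # w2 on -ln KDE_t(phi, psi)
  entropy_sidechain: 1.0
  peptide_violation: 1.0
  sidechain_violation: 1.0
exposure:
  kappa: 0.085              # occlusion decay constant
  shell_radius: 5.0         # sigmoid midpoint r0 of the neighbour weight
  sharpness: 0.5            # sigmoid width lambda
electrostatics:
  cutoff: 12.0              # A, charged-pair collection radius
  min_distance: 0.001       # A, clamp to avoid division blow-up
hbond:
  d_optimal: 1.9            # A, H...acceptor well minimum
  d_sigma: 0.25             # A, width of the distance well
  cutoff: 3.5               # A, H...acceptor collection radius
  dha_power: 3              # exponent on the D-H...A cosine factor
  lp_sigma_deg: 35.0        # width of the lone-pair (acceptor-angle) factor
  lp_optimal_sp2: 120.0     # deg, optimal H...A-antecedent angle, sp2 acceptor
  lp_optimal_sp3: 109.5     # deg, sp3 acceptor
  softmin_tau: 0.1          # kcal/mol, acceptor soft-selection temperature
disulfide:
  d_optimal: 2.05           # A, S-S bond length
  d_sigma: 0.15             # A
  cutoff: 2.5               # A, SG-SG collection radius
clash:
  pair_cutoff: 5.0          # A, pair-collection radius
  slope: 10.0               # exponent prefactor of the penalty
  min_group_count: 50       # calibration sample floor per group
  continuous: false         # subtract w on the active branch if true
sidechain_entropy:
  hbond_threshold: 0.3         # kcal/mol of H-bond magnitude that locks
  hbond_tau: 0.08              # smoothness of the H-bond gate channel
  strong_elec_threshold: -1.0  # kcal/mol pair energy that gates full cost
  gate_tau: 0.25               # kcal/mol, smoothness of the elec channel
  disulfide_threshold: 0.5     # kcal/mol of S-S magnitude that locks
  disulfide_tau: 0.1
density:
  min_samples: 100
  max_centers: 5000
  bandwidth_factor: 1.0     # multiplier on the circular Silverman bandwidth
  floor: 1.0e-12            # density floor before log
peptide:
  sigma_floor: 0.001        # native units (rad or A)
  break_distance: 2.5       # A, N-Cp beyond this flags a chain break
radii:                      # per element, A
  "H": 1.10
  "C": 1.70
  "N": 1.55
  "O": 1.52
  "S": 1.80
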