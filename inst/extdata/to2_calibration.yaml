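# Calibration table for the reduced-dimensional 2-thiooxazole (2-TO)
# excited-state surrogate.  Pinned energetics are gas-phase ADC(2)-level
# reference values; quantities marked "chosen" are package defaults for
# parameters no reference prints (documented in the methods vignette).
schema: surfhop-calibration/1
name: to2_gasphase

reference_geometry:        # S0 equilibrium, internal coordinates
  r_CO: 1.37               # Angstrom, C(2)-O ring bond
  r_CS: 1.64               # Angstrom, thiocarbonyl C=S
  theta_tilt: 0.0          # degrees, C-S tilt out of the ring plane
  r_NH: 1.01               # Angstrom

effective_masses:          # amu; theta_tilt carries a moment-of-inertia
  r_CO: 6.862              # derived effective mass (amu A^2/deg^2) so that
  r_CS: 8.726              # kinetic energies are consistent across
  theta_tilt: 0.026272     # coordinates
  r_NH: 0.940

vertical_energies_eV:      # adiabatic singlet excitations at the reference
  S1: 4.23                 # dark n-pi*
  S2: 4.64                 # bright pi-pi*
  S3: 5.06                 # pi-sigma*

oscillator_strengths:      # per diabat, dimensionless
  n_pi*: 3.65e-5
  pi_pi*: 0.364
  pi_sigma*_CO: 0.022      # the S3 pin rides on the C-O repulsive state
  pi_sigma*_NH: 0.010      # chosen (not printed)

triplet_vertical_energies_eV:   # chosen defaults (not printed); ordering
  T1: 3.60                      # pi-pi* below n-pi*
  T2: 4.10

triplet_pi_sigma_CO_vertical_eV: 5.0   # chosen; repulsive sigma* states have
                                       # near-degenerate singlet/triplet flavors

barriers_eV:               # E(MECP) - E(preceding excited-state minimum)
  S1_tilt: 0.3             # S1 min -> n-pi*/S0 crossing (C-S tilt, puckering)
  S1_CO: 0.4               # S1 min -> pi-sigma*_CO/S0 crossing
  T1_tilt: 0.2             # T1 min -> pi-pi*/S0 crossing
  T1_CO: 0.2               # T1 min -> pi-sigma*/S0 crossing (C-O fission)

excited_state_geometry:
  d_r_CS: 0.13             # C-S elongation of excited-state minima, Angstrom
  theta_tilt: 30.0         # tilt of excited-state minima, degrees (chosen)

co_crossing_window_A: [1.8, 2.0]   # pi-sigma*_CO/S0 crossing location in r_CO

couplings:
  diabatic_eV: 0.15              # constant, between excited same-multiplicity diabats
  ground_diabatic_eV: 0.0        # closed-shell S0 diabat is uncoupled
  soc_cm1: 50.0                  # effective singlet-triplet coupling
  soc_same_character_factor: 0.1 # El-Sayed-like damping for same-character pairs

tolerance_eV: 0.02         # per-pin calibration tolerance
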