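# permeonics demo pipeline: Brownian pore simulation + full analysis chain.
# All randomness flows from the single top-level seed.
seed: 7
temperature: 303        # K
output_dir: permeonics_out
span: [-10, 10]         # filter region along z (Angstrom)
stages: [simulate, permeation, occupancy, rdf]

simulate:
  n_frames: 20000
  dt: 0.0005            # ns
  n_ions: 3
  voltage: 0.6          # V; field along +z
  ion_charge: 2         # e (divalent calcium)
  well_positions: [-5, 5]
  well_depths: [4, 4]   # kT
  well_width: 1.5       # Angstrom
  diffusion_coeff: 50   # A^2/ns
  coupling_strength: 10 # kT*A screened ion-ion repulsion
  screening_length: 3   # Angstrom
  box: [40, 40, 70]     # Angstrom

occupancy:
  dz: 0.5

rdf:
  partner_roles: ion    # simulated trajectories carry ions only
  r_max: 8
  dr: 0.2
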