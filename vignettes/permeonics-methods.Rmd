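---
title: "Methods: ion permeation, solvation and charge-transfer analysis"
author: "permeonics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion permeation, solvation and charge-transfer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

permeonics analyzes simulations of divalent-cation conduction through ion
channels at two levels: classical trajectory statistics (permeation events,
conductance, occupancy and free-energy maps, hydration structure) and
electronic-structure analysis of the conducting ion's first solvation shell
(charge transfer and localized-orbital polarization). This vignette records
the models, conventions and numerical choices behind each stage, and what
the synthetic generators do and do not emulate.

## Conventions and units

Coordinates are in Angstrom, time in nanoseconds, charge in units of the
elementary charge, electron densities in e/A^3. The pore axis is z with +z
the outward (extracellular) direction. Boxes are orthorhombic; triclinic
input is rejected explicitly rather than silently mishandled. Energies from
trajectory statistics are in units of kT at the configured temperature
(default 303 K, the simulation temperature of the study systems), with
kJ/mol conversions provided. Dipoles use 1 e.A = 4.80320 D. Gaussian cube
files follow the Bohr-sign convention of the standard and are converted on
read.

## Permeation events and conductance

An ion is in one of three states relative to a `channel_span(z_lower,
z_upper)`: below, inside, or above. A permeation event is recorded only when
the state sequence traverses below -> inside -> above (outward) or the
reverse (inward); an excursion that re-exits on its entry side counts
nothing. This hysteresis makes the count robust against boundary jitter,
which a single-plane crossing detector would double-count. An event is
attributed to the frame where the ion first appears on the far side.

Two practical complications are handled explicitly:

* **Periodic recycling.** In computational-electrophysiology-style setups a
  permeated ion reappears in the opposite bulk reservoir. Any step with
  |dz| > box_z/2 is treated as a periodic image jump: the detector adopts
  the new side without arming, so recycling can never produce an event.
  Unwrapping assumes ions move less than box_z/2 between frames; when a
  non-wrap step exceeds box_z/4 a warning flags too-coarse frame spacing.
* **Single-frame traversals.** A non-wrap step that hops directly from
  below to above is a physical crossing at the available time resolution
  and counts as one event. This keeps the event count invariant under
  moderate frame thinning.

Conductance follows from counts: I = n * q * e / t with n the net
(outward - inward) count by default; G = I / V in pS. Whether net or
outward-only counting is appropriate is a user decision (`counting=`); net
is the default because reverse crossings genuinely reduce transported
charge. Replica statistics use the sample (n-1) standard deviation, the
convention for a handful of independent runs.

## Occupancy, concentration and free energy

Ion positions are accumulated into axial bins (1D) or axial-radial (z, r)
bins (2D); the 2D map is an azimuthal average about the pore axis, which is
the statistically efficient reduction of a planar occupancy map for a
cylindrically confined ion pathway. Number density uses the true bin volume
(lateral box cross-section, a cylinder cross-section, or annular shells),
converting to mol/L via 1 A^-3 = 1660.54 mol/L. Boltzmann inversion gives
F = -kT ln(rho / rho_max): the reference is the most occupied bin, so the
minimum of F over occupied bins is exactly zero; empty bins are reported as
NA rather than an infinite sentinel. Relative 1D occupancy (density divided
by its maximum) is the axis used for comparing binding profiles between
ions.

## Hydration statistics

The radial distribution function uses minimum-image distances and spherical
shell volumes; the running coordination number n(r) is computed by direct
counting, never by integrating g(r), so it is exact regardless of shell
discretization. The reference density defaults to (partner count)/(box
volume); inside a pore this is not a bulk density, so g(r) plateaus need
not be 1 - the number that is directly interpretable there is n(r).
Conditioning on an axial window (for example, the ion at a stated filter
depth) restricts the (frame, center) samples; the window half-width
defaults to 1 A and is configurable since narrower windows trade bias for
variance. Coordination counting uses a closed boundary (a partner exactly
at the cutoff counts) with a 3.2 A default first-shell cutoff - the region
of the first minimum beyond the 2.4 A Ca-O contact peak. Protein contacts
are counted as distinct residues (molecule ids) with at least one oxygen
within the cutoff, matching how channel coordination is usually reported.

## Electron-density differences and Voronoi charge transfer

Polarization and charge transfer in the first shell are quantified from
three electron densities on one grid: the full complex, the bare ion
(ligand), and the complex without the ion (rest). The deformation density
is their voxel-wise difference; positive values mean electron gain upon
binding. The three grids must be congruent (origin, voxel vectors, shape
within 1e-6 A); no resampling is performed, because interpolation
introduces quadrature bias precisely where the difference density is
sharpest.

Per-atom charges integrate the deformation density over Voronoi cells:
every grid point is assigned to its nearest atom (ties, which can only
occur for points exactly on a cell boundary, go to the lowest atom index,
making the partition deterministic, exhaustive and exclusive - per-atom
integrals sum to the total grid integral to machine precision). The ion's
effective charge is its nominal charge minus the electrons gained in its
cell; per-water donation is the negative of the summed per-atom gains of
that water.

A practical quadrature point: each fragment density contains sharp nuclear
cusps that a uniform cube grid undersamples badly, but because all three
densities are evaluated at identical points the error cancels in the
difference wherever core orbitals barely relax. The residual noise scale
can be checked by shifting the grid origin; at 0.1 A spacing with the grid
offset so that no nucleus lies on a grid plane, the per-atom integrals of
the difference density are stable to about 1e-3 e.

## Localized orbital centers, shifts and dipoles

Center classification assigns each localized-orbital (Wannier-style) center
to the molecule of its nearest oxygen (within 1.2 A) and labels it an O-H
bond center when the angle between O->center and O->H falls below 35
degrees for either hydrogen, else a lone pair. The 1.2 A radius and 35
degree cone sit halfway between the typical bond-center geometry (about 0.5
A from O along the bond) and lone-pair geometry (about 0.3 A from O, about
55 degrees out of the bond plane), and both are configurable.

Center shifts between two states (for example with and without the
coordinating ion at identical water geometry) pair centers within each
(molecule, kind) group by minimum total distance, then project the
displacement (perturbed minus reference): lone pairs onto the O->ion unit
vector (positive toward the ion), bond centers onto the H->O unit vector
(positive toward the oxygen, the direction that makes the O-H bond more
polar).

Molecular dipoles use the valence point-charge picture: mu = 6 r_O + r_H1 +
r_H2 - 2 sum(r_center) over the four valence centers, in e.A. The O:+6,
H:+1 valence charges follow the pseudopotential convention; with exactly
four doubly occupied centers the molecule is neutral and the dipole is
origin independent (asserted under random translations in the tests).
Because the sum of localized-orbital centroids is invariant under the
unitary localization, this point-charge dipole reproduces the quantum
mechanical dipole expectation value up to the small displacement of the
core centroid from the nucleus.

## The quantum-chemistry engine

The electronic inputs (cube densities and localized centers) are produced
by a compact self-contained engine rather than an external code:

* **Integrals.** McMurchie-Davidson Gaussian integrals (overlap, kinetic,
  nuclear attraction, dipole, two-electron) over individually normalized
  Cartesian functions up to d, in C++, with a tabulated Boys function
  (Taylor interpolation plus downward recursion) and Schwarz screening.
* **Basis sets, generated in-package.** For H and O, occupied atomic
  shells are Slater-type orbitals with Slater's-rule exponents (H scaled
  1.24, the standard molecular value), each least-squares expanded in
  Gaussians (the classical STO-nG construction, fit numerically at build
  time and memoised); valence shells are split, and oxygen gets its three
  2p fit primitives uncontracted plus an even-tempered diffuse p
  continuation and a d polarization function (exponent 0.8). Calcium uses a
  variationally optimized even-tempered 12s8p primitive set (atomic ion
  energy -676.10 Hartree against the -676.57 limit), general-contracted to
  the atomic 1s/2s/3s and 2p/3p orbitals with the two outermost s and p
  primitives left free and a d acceptor/polarization pair tracking the free
  p exponents - the flexibility near the ion matters because donated
  density must be representable inside the ion's Voronoi cell. On water
  this basis gives an SCF energy of -75.696 Hartree (Hartree-Fock) and a
  dipole of 2.24 D, matching the behavior of standard split-valence plus
  polarization sets; the engine reproduces published minimal-basis
  references exactly (H2 at -1.1167 and water at -74.9629 Hartree with
  textbook exponents).
* **SCF.** Closed-shell RHF or hybrid-DFT with DIIS and a
  Wolfsberg-Helmholz guess. The density-functional layer evaluates a
  B3LYP-style hybrid (20% exact exchange, 0.08/0.72 Slater/B88 exchange,
  0.19/0.81 VWN5/LYP correlation) on a Becke-partitioned atom-centered
  grid (Gauss-Chebyshev radial shells, product Gauss-Legendre angular
  shells, fuzzy-cell weights). Exchange-correlation potentials are obtained
  by finite differences of the energy density, which for these smooth
  functionals is accurate far beyond the SCF threshold and eliminates an
  entire class of derivative bugs. The functional implementations are
  validated against the helium anchors they were historically fit to
  (B88 exchange -1.025, LYP correlation -0.0437 Hartree on the He
  Hartree-Fock density).
* **Localization.** Boys localization by Jacobi 2x2 rotations of the
  occupied orbitals; orbital centroids are the centers. Core centroids
  (within 0.1 A of a heavy nucleus) are dropped before classification.

The hybrid-DFT level matters for the charge-transfer observables: at the
Hartree-Fock level the net electron gain in the ion's Voronoi cell is an
order of magnitude smaller, while intramolecular O/H polarization is
similar. The B3LYP-style functional is therefore the default for the
charge-transfer and localized-center analyses.

## The Brownian pore simulator

The synthetic trajectory generator is an overdamped Langevin model of the
permeation pathway: motion along z in a potential of Gaussian binding wells
(depths in kT, one per site) plus a constant field E = V/box_z, lateral
diffusion inside a reflecting cylinder, periodic recycling along z, and a
screened pairwise repulsion A exp(-d/lambda)/d between ions that produces
loosely coupled knock-on behavior (an incoming ion expels the occupant of a
binding site). Knock-on is asserted as a conditional-probability contrast:
in a blocked regime (one deep binding site, moderate voltage) the
probability that a filter entry is followed within a short lag by an exit
through the top is an order of magnitude larger with the repulsion switched
on than in an uncoupled control with identical settings. The contrast is
measured against that control rather than against a shuffled baseline
because depletion of the finite ion pool biases within-trajectory baselines.
Defaults emulate the study conditions: divalent ions, 600 mV,
303 K, two principal binding sites (z = -5 and +5 A, 4 kT deep, width
1.5 A), a 70 A box, and a diffusion coefficient of 50 A^2/ns (bulk calcium
is about 79 A^2/ns; confinement reduces it). The integrator enforces
sqrt(2 D dt) < well_width/4 and suggests a stable dt otherwise.

What the simulator emulates: event statistics with binding-site pauses,
field-driven drift obeying the Einstein relation, occupancy maps with
well-defined free-energy minima, and knock-on correlations. What it does
not: water dynamics, a real channel geometry, ion-specific chemistry, or
quantitative conductances of any particular channel - passing tests on
synthetic trajectories validates the estimators, not force fields.

## Problem sizes and numerical choices

The bundled analyses and tests run on deliberately modest sizes chosen as
the smallest that make the statistical assertions sharp: simulator checks
use 2e5 to 1e6 steps at dt = 2-5e-4 ns; radial-distribution checks use 1000
ideal-gas atoms over 50 frames; cube-based checks use 49^3 to 129^3 grids
at 0.1-0.25 A spacing. The quantum-mechanical reference cluster is a
single Ca(H2O)7 configuration (7-fold first shell at the 2.4 A contact
distance, water dipoles oriented toward the ion), the coordination motif
the permeation simulations find; its SCF spans 204 basis functions
(exchange-correlation quadrature on 40 radial x 128-200 angular points per
atom, and the complex SCF started from the superposition of the converged
fragment densities). A
production study would average such analyses over many snapshots; the
acceptance pipeline analyzes one constructed geometry and so carries
configurational bias a thermal average would reduce.

Degenerate inputs are errors, not guesses: empty selections, all-empty
occupancy profiles, spans wider than the box, non-congruent grids,
non-axis-aligned cube vectors, odd electron counts and infeasible fixture
dipoles all fail with messages naming the offending field.
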