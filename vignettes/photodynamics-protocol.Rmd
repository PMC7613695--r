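---
title: "Nonadiabatic photodynamics on an analytic 2-thiooxazole surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonadiabatic photodynamics on an analytic 2-thiooxazole surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The protocol

`surfhop` implements the complete desk-scale workflow used to explain the
photodegradation of 2-thiooxazole (2-TO), a five-membered O/N
heteroaromatic bearing a thiocarbonyl group that is discussed as a
prebiotic precursor of thiolated RNA nucleotides:

1. harmonic **Wigner sampling** of ground-state geometries and momenta;
2. a **nuclear-ensemble absorption spectrum** from vertical excitation
   energies and oscillator strengths;
3. selection of **initial conditions** inside an excitation window around
   the band maximum;
4. **fewest-switches surface hopping** (FSSH) across coupled singlet and
   triplet manifolds with effective spin-orbit coupling and the
   energy-based decoherence correction;
5. **termination and channel classification** of each trajectory;
6. **LIIC profiles, relaxed scans and penalty-function MECP
   optimization** for the stationary-point picture of the same channels.

All electronic structure comes from an analytic coupled diabatic model
(`surface_model`), so every stage is testable without quantum chemistry.
The shipped surrogate is calibrated to the published gas-phase energetics
of 2-TO; the FSSH, spectrum and path machinery are generic and accept any
`surface_model`.

## The surrogate landscape

Four internal coordinates carry the photochemistry: the C(2)–O ring bond
`r_CO` (rupture is the photodestructive channel), the thiocarbonyl C=S
stretch `r_CS`, the C–S out-of-plane tilt `theta_tilt` (the
photostabilising motion, degrees) and the N–H stretch `r_NH`.  Each
coordinate has an effective mass in amu (reduced masses of the atom
pairs: 6.862, 8.726, 0.940; for the tilt a moment-of-inertia-derived
value, 0.0263, so that kinetic energies are consistent across
coordinates).

Eight diabats span the landscape: the closed-shell ground state, a dark
n-pi* and a bright pi-pi* singlet, repulsive pi-sigma* states along C–O
and N–H, triplet pi-pi* and n-pi* analogues, and a triplet flavor of the
repulsive pi-sigma*(C–O) state.  Diagonal entries are sums of
one-coordinate closed forms — Morse wells for bond stretches,
harmonic terms in `r_CS`, a symmetric double well in the tilt for the
bound excited states (minima at ±30°), quadratic-plus-quartic tilt
resistance for the ground state, and exponential walls for the
pi-sigma* states — so diabatic gradients are exact and adiabatic
gradients follow from the Hellmann–Feynman theorem.  Off-diagonal
couplings are constants: 0.15 eV between excited diabats of equal
multiplicity and an effective spin-orbit coupling of 50 cm⁻¹ between
manifolds, damped tenfold for same-character pairs (an El-Sayed-like
rule).  All of these are config-exposed in
`inst/extdata/to2_calibration.yaml`.

Design choices worth spelling out:

* **The closed-shell diabat is uncoupled** (coupling 0 by default).  With
  a 0.15 eV coupling to S0 the adiabatic S1–S0 gap could never drop below
  0.30 eV, so neither the 0.15 eV termination criterion nor MECP gap
  closure would ever fire.  Crossings with S0 are therefore genuine
  degeneracies, standing in for conical intersections.
* **The repulsive pi-sigma*(C–O) state appears in both manifolds.**  With
  a purely bound triplet pi-pi* state and separable terms, the triplet
  C–O-fission and tilt seams merge into one mixed crossing point:
  tilting simultaneously lowers the triplet and raises S0, so a distinct
  planar C–O seam basin cannot exist.  Since sigma* repulsive states have
  nearly degenerate singlet/triplet flavors and the C–O channel is
  observed in both manifolds, the triplet copy (vertical 5.0 eV, f = 0)
  restores the correct seam topology.
* **The accessible low-lying pi-sigma* is the C–O one.**  The tabulated
  third singlet (5.06 eV, f = 0.022) is assigned to pi-sigma*(C–O); the
  N–H repulsive state is placed at 5.5 eV (chosen).  With the opposite
  assignment the dynamics produce N–H fission as the dominant channel and
  almost no singlet ring opening, the reverse of the reference picture in
  which C–O fission dominates with a ballistic sub-population inside
  50 fs.
* **A tilt funnel connects S2 to S1.**  The bright pi-pi* diabat carries a
  deep tilt well (0.55 eV) and the dark n-pi* a shallow one (0.10 eV), so
  the two cross near 27°; the planar Franck–Condon point is a tilt
  maximum of the excited surfaces and population slides into the crossing
  within tens of fs.  The triplet n-pi* has its well at 15°, steeper
  beyond, which provides the analogous triplet crossings.

### Calibration

`build_to_surrogate()` pins, within 0.02 eV each: the three adiabatic
singlet verticals (4.23, 4.64, 5.06 eV), the chosen triplet verticals
(3.60, 4.10 eV), and four crossing barriers measured as E(MECP) − E(the
preceding excited minimum): 0.3 eV (S1 → n-pi*/S0 tilt seam), 0.4 eV
(S1 → pi-sigma*/S0 C–O seam), 0.2 eV and 0.2 eV for the two triplet
analogues.  It also pins the +0.13 Å C–S elongation of the excited
minima and requires the singlet C–O crossing at 1.8–2.0 Å.

Verticals are matched by a fixed point on the diabatic origins (the
constant couplings shift adiabatic energies, so origins are iterated
until the eigenvalues sit on the pins; the assignment n-pi* → S1,
pi-pi* → S2, pi-sigma*(CO) → S3, pi-pi* → T1, n-pi* → T2 is held fixed,
which keeps the iteration stable when wells deepen).  Four shape
parameters are then tuned by root finding, each evaluated through a full
penalty-function MECP optimization: the ground-state tilt quartic (sets
the singlet tilt barrier), the pi-sigma*(C–O) repulsion amplitudes in
each manifold (set the two C–O barriers at fixed verticals) and the
depth of the T1 tilt well.  Seam searches are seeded from a coarse grid
inside channel-specific coordinate boxes, because the crossing seam is
connected and an unconstrained search can drift between basins.  The
whole calibration is deterministic (no random numbers) and takes about a
minute; the result is cached per session (`to2_default_model()`) and can
be exported/imported with `write_surface_model()` for byte-reproducible
downstream runs.

## Initial conditions and spectrum

Sampling uses the ground-vibrational-state Wigner density of the
harmonic modes at the S0 minimum (analytic-gradient Hessian, four modes
at roughly 83, 1090, 1940, 3670 cm⁻¹): independent Gaussians with
variance 1/2 in the dimensionless mode variables, transformed to
coordinates and momenta.  Sampling is at 0 K — no thermal excitation —
matching common practice for this protocol.  The default ensemble is 500
geometries.

The spectrum is the oscillator-strength-weighted sum of normalized
Gaussians (default FWHM 0.1 eV; the reference does not state its
broadening, and 0.1 eV visually matches the published bandwidth), so the
integrated intensity equals the mean total oscillator strength;
intensities are reported in arbitrary units because only the band
position and window overlap are consumed downstream.  The surrogate band
peaks near 4.6 eV, slightly red of the 4.64 eV vertical because the
excited wells are softer than the ground state along every coordinate.

Window selection implements the standard stochastic-selection rule:
every (sample, excited singlet) pair with vertical energy inside
4.5–4.7 eV is accepted with probability f/f_max, where f_max is the
largest in-window strength.  A sample may contribute conditions on more
than one state.  On the surrogate the bright pi-pi* adiabat dominates
the accepted set, with a minority on S3 and essentially none on the dark
S1 — same character split as the reference ensemble, whose counts
(120/16/5 of 141) the bookkeeping helpers reproduce as 85/11/4 percent.

## Dynamics

Nuclei follow velocity Verlet (0.5 fs) on one spin-adiabatic surface
(eigenstates of diabatic + SOC potential).  Electronic amplitudes are
propagated with 25 substeps per nuclear step (0.02 fs), linearly
interpolated energies and a constant coupling matrix obtained from the
Löwdin-orthonormalized overlap of consecutive eigenvector sets,
`T = (S − Sᵀ)/(2Δt)`.  The stiff dynamical phase is removed analytically
(interaction picture) before RK4 integration, which keeps the
propagation norm-preserving to ~1e-8 per step at production settings.
Fewest-switches hop probabilities are accumulated substep by substep;
accepted hops rescale the momenta along the velocity direction to
conserve total energy exactly (the overlap scheme yields scalar
couplings, so no coupling vector is available for rescaling; frustrated
hops keep the momentum unchanged).  The energy-based decoherence
correction damps inactive amplitudes with
`tau = (hbar/|ΔE|)(1 + C/E_kin)`, C = 0.1 Hartree, and restores the norm
exactly; degenerate states and zero kinetic energy give infinite
lifetimes rather than errors.

Two protocol rules shape the ground-state return.  Hops into the
closed-shell surface are disabled; instead a trajectory terminates by
assumed internal conversion when the active singlet's gap to the
closed-shell surface drops below 0.15 eV, and as triplet-trapped when a
triplet does the same (the reference electronic-structure method is
unreliable near ground-state intersections, and singlet–triplet
repopulation of S0 cannot be modelled without explicit sublevels).  The
closed-shell surface is identified by diabat weight, not by energetic
position — on a dissociative branch the repulsive state falls *below*
the closed-shell curve, and the signed gap then triggers the same
termination.

Because the S0 crossings are exact degeneracies, a trajectory can pass a
crossing within one 0.5 fs step.  The propagator therefore tracks
trivial crossings through the overlap matrix: if the active adiabat
swaps character with a neighbour within a step (maximal overlap off the
diagonal), the active index follows the character without a stochastic
hop — the amplitudes are carried through the swap by the propagation
itself.  Without this, dissociating trajectories ride the wrong adiabat
past the seam and never terminate.

Two engines implement the identical algorithm: a reference R
implementation built from the exported single-step operations and a
compiled RcppArmadillo propagator (the default).  Both consume one
uniform draw per nuclear step from R's RNG, so for a given seed they
produce matching trajectories (asserted to 1e-8 in the tests); a
141-trajectory, 1000 fs ensemble takes well under a minute with the
compiled engine.  Ensemble seeds are derived deterministically from the
master seed, so trajectories are independent of execution order.

## Paths and crossing points

`liic_path()` interpolates each internal coordinate linearly between
anchor geometries and accumulates the mass-weighted path coordinate
`Σ sqrt(Σ_i m_i Δq_i²)` (amu^0.5 Å); `relaxed_scan()` minimizes the
orthogonal coordinates on one spin-pure surface at each scan value,
warm-started from the previous point.  `optimize_mecp()` minimizes the
smoothed penalty objective
`(E_i + E_j)/2 + σ (E_i − E_j)²/(|E_i − E_j| + α)` with σ doubling from
3.5 and α = 0.02 Hartree until the gap closes below 1 meV and the
seam-projected mean-energy gradient falls below 1e-3 eV per coordinate
unit (the reference method cites no settings; these defaults converge in
a handful of penalty updates on convex seams and are insensitive to the
starting σ).  Crossings between manifolds are optimized on spin-pure
surfaces — SOC excluded — the conventional choice; optional coordinate
boxes (L-BFGS-B) select a seam basin where several exist.  Barriers are
reported relative to the preceding excited-state minimum.

## What the surrogate does and does not show

The calibrated model reproduces the *energetics* (verticals, barriers,
crossing locations) and the *mechanistic topology* (tilt funnel, twin
photostabilising/photodestructive seams in both manifolds, minor N–H
channel) of the reference landscape.  Ensemble observables that emerge
from the dynamics come out qualitatively right but not quantitatively:
ring opening along C(2)–O and the photostabilising channel are
co-dominant near 40% each (reference: 50% and 37%), N–H fission is minor
(~10% vs 13%), and with 141 trajectories the identity of the modal
channel can flip between seeds.  The triplet-manifold share is 10–20%
against the reference 32%: the single effective SOC constant replaces
three magnetic sublevels, and four modes concentrate the vibrational
excess energy that 21 modes would share, shortening singlet residence
times near the crossing seams.  Passing tests therefore demonstrate the
correctness of the machinery and the calibrated energetics, not
quantitative channel statistics of the real molecule.

Numerical choices and degenerate inputs: exponential term arguments are
clipped at ±60 so optimizer excursions stay finite; overlap matrices far
from orthogonal (|det| < 0.5) trigger one midpoint-chained retry and
then a `failed` flag; failed trajectories stay in the ensemble, counted
but excluded from statistics; an empty excitation window returns an
empty selection, not an error; imaginary frequencies are carried by the
file formats but rejected by the sampler by mode index.

## Problem sizes

The shipped defaults are the study conditions: 500 Wigner samples, a
4.5–4.7 eV window, up to 141 trajectories of at most 1000 fs at
0.5/0.02 fs steps.  The test suite exercises reduced ensembles (tens of
trajectories, shorter horizons) for unit properties and the full
141-trajectory ensemble once; the statistical oracles use 1e5 Wigner
samples and 2000 Landau–Zener trajectories.

## A worked run

```{r}
library(surfhop)

model <- to2_default_model()          # calibrated surrogate (cached)
modes <- normal_modes(model)
wig   <- sample_wigner(modes, 500, seed = 1)
spec  <- ensemble_spectrum(wig, model, window = c(4.5, 4.7))
attr(spec, "peak_eV")

ics <- select_excitation_window(wig, model, window = c(4.5, 4.7), seed = 2)
ens <- run_ensemble(ics, model, dynamics_config(seed = 3))
summarize_ensemble(ens)

pop <- adiabatic_populations(ens)
prof <- liic_path(model, list(model$meta$anchors$s0_min,
                              model$meta$anchors$s1_min,
                              model$meta$anchors$mecp_s1_co),
                  anchor_labels = c("S0 min", "S1 min", "MECP"))
```
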