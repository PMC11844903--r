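---
title: "Coarse-grained condensate models and the characterization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained condensate models and the characterization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model family

cgphase implements six residue-resolution coarse-grained models for
intrinsically disordered proteins: HPS, HPS-cation-π, HPS-Urry,
CALVADOS2, Mpipi and Mpipi-Recharged. Each protein is a bead-spring
chain, one bead per amino acid, in implicit solvent; the dilute phase in
a direct-coexistence simulation is therefore effectively a vapour. The
potential energy decomposes into bonds, electrostatics, a hydrophobic
(dispersion) term and, for HPS-cation-π only, an extra cation-π term.

**Bonds** are harmonic, `E = k (r − r0)²` with no ½ factor; `r0 =
3.81 Å` is the Cα–Cα virtual bond length and `k` is 9.6 kJ mol⁻¹ Å⁻²
except for HPS-cation-π (2.4) and HPS-Urry (4.8). Directly bonded pairs
are excluded from all nonbonded terms, the convention of the reference
implementations of these models; the bead masses are the standard
amino-acid residue masses.

**Electrostatics.** Charged residues (R, K: +1; D, E: −1; histidine is
kept neutral — the models differ upstream in how they titrate H, and a
pH model is out of scope) interact through a Debye–Hückel potential.
The screening parameter is fixed at κ = 1 nm⁻¹ (HPS family, representing
~150 mM monovalent salt with ε_r = 80) or 1.26 nm⁻¹ (Mpipi). CALVADOS2
and Mpipi-Recharged instead derive κ from the salt concentration via the
Bjerrum length, with the relative permittivity following an empirical
ε_r(T) law (a 1/T term plus a cubic polynomial, ≈78.4 at 298.15 K,
monotonically decreasing over the 230–450 K validity window we enforce).
Mpipi-Recharged replaces the charge-product numerator by a pair-specific
Yukawa amplitude A_ij; we retain i↔j symmetry and read "pair-specific"
as "not reducible to a product of single-residue charges".
Electrostatic cutoffs: 3.5 nm by default, 2.0 nm for HPS-Urry, 4.0 nm
for CALVADOS2.

**Hydrophobic term.** The HPS family and CALVADOS2 use the two-branch
Ashbaugh–Hatch form: full Lennard-Jones shifted up by (1 − λ_ij)ε below
the minimum at 2^{1/6}σ_ij, and λ_ij-scaled LJ beyond it; the two
branches join continuously at −λ_ij ε. λ and σ mix by Lorentz–Berthelot
rules, ε = 0.2 kcal/mol = 0.8368 kJ/mol. The λ scale distinguishes the
models: Kapcha–Rossky for HPS and HPS-cation-π (ranking F > W > Y), Urry
for HPS-Urry and the optimized CALVADOS2 scale (both W > Y > F). The
Mpipi family uses the Wang–Frenkel potential with per-pair ε, σ and ν,
μ = 1 and cutoff r_c = 3σ_ij; the normalizer α (exponent 2ν + 1) makes
the minimum depth exactly −ε_ij, a property the test suite verifies
numerically to 10⁻⁸. All hydrophobic terms are truncated at 3σ_ij.

**Tail treatment.** Potentials are plainly truncated at their cutoffs,
not shifted — the default of the MD engines these models are usually run
in. The residual discontinuity (≈0.01–0.02 kJ/mol per crossing for AH)
is irrelevant for thermostatted dynamics but visible in microcanonical
energy conservation; the NVE conservation test therefore uses a cold
bound cluster whose pair distances stay away from the cutoffs.

## Parameter tables and their provenance

Residue tables (charge, λ, σ, mass) and pair tables ship as commented
CSVs under `inst/extdata/params/`, with a YAML registry mapping each
model to its scheme flags, constants and cutoffs. The hydropathy scales,
bead diameters, charges and masses are transcriptions of widely
reproduced published values; they should be diffed against the upstream
model releases before any production use. The Mpipi/Mpipi-Recharged
per-pair tables and the HPS-cation-π well depth are **synthetic
surrogates** (filenames say so): the true tables are defined only in the
original model publications, so we generate tables that preserve the
documented qualitative structure — pair-specific energies off the
mixing-rule manifold, the W > Y > F aromatic hierarchy, strong R–aromatic
and weak K–aromatic cation-π energies for the Mpipi family, a uniform
enhanced cation-π well (≈4× the aromatic AH depth) for HPS-cation-π, and
Yukawa amplitudes with the sign structure of the charge product
modulated pair-specifically. Everything that depends only on this
qualitative structure (orderings, matrix normalization, scheme dispatch)
is faithful; absolute Mpipi-family energies are not.

The packaged A1-LCD variant family is likewise a synthetic surrogate
sequence set (137 residues): 19 mutable aromatic "sticker" positions
spaced every 7 residues carrying 7 Y + 12 F in the reference, one
additional non-mutable Y in an NLS-like C-terminal tail (total 8Y + 12F),
and spacers drawn from a fixed G/S/N/Q/R/D/K cycle. Variants mutate only
the sticker positions (allF/allY/allW/YtoW/FtoW; W− converts 13 stickers
to W and 6 to G), conserving patterning. The printed aromatic counts of
the variant family are reproduced at the sticker positions; note that no
assignment of the 20th aromatic can make *whole-sequence* counts of 19
consistent for both allF and allY, which is why the package reads the
variant counts as sticker-position counts.

# The simulation engine

Dynamics are BAOAB-splitting Langevin in the NVT ensemble: half kick,
half drift, Ornstein–Uhlenbeck velocity refresh, half drift, half kick,
with one force evaluation per step. Defaults are a 10 fs timestep and a
5 ps thermostat relaxation time; with the thermostat off the integrator
reduces exactly to velocity Verlet. The thermostat RNG is an internal
mt19937_64 seeded from the settings, so trajectories are bit-reproducible
and independent of R's RNG state. Neighbour search uses a Verlet pair
list (default skin 0.3 nm) rebuilt by an O(N²) pass whenever any bead
has moved more than half the skin; at the desk scales this package
targets (≲ a few thousand beads) the rebuild is not rate-limiting, which
is why we chose it over a cell list — trajectories are invariant to the
skin by construction and the suite asserts it.

System builders place self-avoiding random-walk chains (cell-grid
insertion, overlap rejection below 0.7 σ_ij, 10³ retries per chain): an
elongated slab box with chain centres restricted to the central 40 % of
the long axis for direct coexistence, or a cubic box compressed to a
target density by staged isotropic rescaling of chain centres of mass
(which preserves bond lengths) interleaved with strong-friction
relaxation. Freshly inserted or rescaled configurations contain
near-threshold contacts, so relaxation stages run at reduced timestep
with a 0.02 nm per-half-step displacement cap — the standard push-off
trick; production dynamics never use the cap.

The virial stress σ = (Σ m v⊗v + Σ f⊗r)/V is accumulated during the
force pass (kinetic plus pairwise and bond terms), emitted in bar, and
checked in the suite against the ideal-gas law and a hand-computed
single-pair virial.

# Phase analysis

Density profiles along the slab axis recentre each frame on the periodic
(circular-mean) centre of mass before averaging, so slab drift does not
smear the plateaus. Coexistence densities come from a double-tanh
interface fit (Levenberg–Marquardt, bounded parameters, starting values
from the profile quantiles); a plateau-averaging alternative is exposed
(`method = "plateau"`) and is what the noisy toy-slab smoke test uses.
A profile whose contrast (max − min)/mean falls below 0.25, or whose
fitted gap is below that fraction of the mean, is reported as single
phase rather than as a density pair. Plateau uncertainties come from a
bootstrap over frames.

The critical point solves the two printed laws jointly — the density gap
raised to α = 3.06 against 1 − T/T_c, and the rectilinear diameter
against T_c − T — by equally weighted least squares. Given T_c both laws
are linear in the remaining parameters, so T_c is profiled with Brent
optimization (bracket: just above the highest simulated temperature to
3× it) and the inner problems are solved exactly; noise-free synthetic
data round-trips to ~10⁻⁹ relative. We implement the exponent placement
exactly as printed (the gap raised to α = 3.06 on the left-hand side);
this is algebraically equivalent to the familiar β ≈ 1/3.06 ≈ 0.327
convention and we do not silently substitute one for the other. The T_c
uncertainty is the half-range of refits on the last two, three and four
temperatures; with two points per temperature (gap and midpoint) the
two-temperature refit is exactly determined, so all subsets are usable.

# Contacts

Two beads on different chains are in contact when their minimum-image
distance is below 1.2 σ_ij — just beyond the potential minimum at
~1.122 σ_ij, so only significantly bound pairs count. Position-resolved
maps accumulate over frames and all distinct chain pairs (the analysis
convention for temperature is 0.95 T_c of the system, recorded in the
output metadata). Contact-energy maps weight each contact by the
hydrophobic + electrostatic pair energy *at the observed distance*,
averaged per frame and chain pair. Ranked type-pair strengths weight the
type-aggregated contact frequency by the pair energy at the potential
minimum, divide by the sequence abundances N_i N_j, flip sign so
attraction is positive, and normalize the largest magnitude to 1; types
absent from the sequence are skipped with a warning.

# Rheology

The relaxation modulus uses the six-component Green–Kubo estimator: the
three off-diagonal stress autocorrelations plus one sixth of the three
normal-stress-difference autocorrelations, under V/(5 k_B T). The 1/6
weighting is implemented exactly as printed; for isotropic Gaussian
stress (⟨NN⟩ = 4⟨σ_xy σ_xy⟩) it coincides with the standard
isotropic-average estimator, and the suite checks the six-component and
single-component estimates against each other. Autocorrelations are
multiple-time-origin averages over every origin in the series, computed
by FFT; no mean subtraction is applied (equilibrium off-diagonal stress
has zero mean, and the degenerate constant-input case then reproduces
its closed form).

The split time t₀ is the earliest lag after which the lightly smoothed
modulus is strictly positive and non-increasing (within a 5 % rise
tolerance, guarding estimator noise) across a one-decade sliding window;
if no such lag exists the function refuses and asks for a longer series.
Maxwell modes sit on a fixed log-equidistant grid of relaxation times
spanning [t₀, t_max], defaulting to 4 modes per decade; amplitudes are
fitted by non-negative least squares (Lawson–Hanson), which prevents the
oscillatory sign-alternating overfits an unconstrained fit produces, at
the cost of a small representation bias when true relaxation times fall
between grid points (≲1 % in viscosity on the dense synthetic cases the
suite checks). An ill-conditioned design triggers a condition-number
warning. The viscosity is the trapezoidal integral of G up to t₀ plus
Σ G_i τ_i; the purely numeric integral is exposed for cross-checking,
and a negative hybrid result is an error, not a value.

Units: stress in bar, volume in nm³, time in ps; G is reported in MPa
and viscosity in mPa·s (1 MPa·ps = 10⁻³ mPa·s). The absolute viscosities
of one-bead-per-residue models underestimate experiment by orders of
magnitude (implicit solvent, no atomic friction), which is why the
benchmarking workflow normalizes by a reference variant before
comparison.

# Benchmark metrics

Observable tables are normalized per source (simulation and experiment
each by their own reference variant). The saturation-concentration
deviation uses a signed per-point denominator log₁₀(x_exp), exactly as
printed: it is units-dependent (values are expected in mM), undefined at
x_exp = 1 (rejected with an error naming the point), and contributes
negatively for x_exp < 1 — documented rather than "fixed". The viscosity
deviation is the RMS of decimal-log differences. Both are zero iff
simulation equals experiment pointwise. Linear fits are ordinary least
squares with the Pearson r.

# Synthetic generators: what they emulate, and what they do not

Each generator inverts one analysis stage exactly, so round-trip tests
have analytic ground truth: coexistence curves solving the two critical
laws (optionally with multiplicative Gaussian noise); stress series as
superposed Ornstein–Uhlenbeck processes, the simplest stationary process
with exponential autocorrelation, amplitude-calibrated so the target
modulus is Σ G_i e^{−t/τ_i} and the normal components carry twice the
off-diagonal variance to satisfy the isotropy relation the six-component
estimator assumes; two-phase slabs with ideal tanh (or step) profiles of
non-interacting beads; and a three-letter sticker–spacer toy model
(S/X/C alphabet, AH + DH terms, sticker ε = 4 kJ/mol ≈ 2.4 k_BT at
200 K) whose 10-chain slab demixes within minutes of CPU time. All
generators record their parameters and seed in a `synthetic_spec`
attribute and regenerate bit-identically.

What passing these tests shows is that the pipeline recovers known
ground truth under idealized conditions. Real condensate data differ in
ways the generators deliberately omit: correlated interface
fluctuations and capillary waves, finite-size and finite-sampling bias
near T_c, stress autocorrelations that are not finite sums of
exponentials, and chain connectivity in the synthetic slabs. Desk-scale
success therefore validates the estimators, not the models' absolute
predictions, which require the cluster-scale campaigns described below.

# Problem sizes and scale

The test suite and acceptance script run at desk scale by design:
≤10-chain toy systems for minutes-long smoke simulations (a 1.5 ns,
200-bead slab), 30-bead systems for oracle comparisons, 2×10⁵-sample
synthetic stress series, and 100-repeat noise studies for the critical
fit. The production protocol the package exposes — 200 chains in a
17×17×120 nm slab (~0.1 g/cm³ mean density), microsecond coexistence
runs per temperature and 3–5 μs bulk runs for G(t), repeated over a
temperature ladder per variant and model — is cluster work: the builders
and the engine accept those sizes, and the LAMMPS writers exist
precisely so such campaigns can be run in a production MD engine and
analysed here. The qualitative desk-scale proxy (mean sticker–sticker
strength ordering allW > allY > allF for the hierarchical models) is
checked in the suite; full phase-diagram orderings are not claimed.

# Known limitations

- Mpipi-family pair tables and the HPS-cation-π depth are surrogates
  (above); absolute energies, critical temperatures and viscosities for
  those models are not comparable to the published parametrizations.
- No angular/dihedral terms, no explicit ions or solvent, no NPT, no
  constraints, no RNA/DNA beads; single-species systems only in the
  contact analysis.
- Truncated-unshifted tails make microcanonical energy conservation
  cutoff-limited (irrelevant under a thermostat).
- The deviation metric for saturation concentrations inherits the
  printed signed denominator; interpret it only for observables > 1 in
  their working units.
- Histidine is neutral in all shipped tables.
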