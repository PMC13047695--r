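---
title: "Methods: NMR restraints for coarse-grained bead models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR restraints for coarse-grained bead models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models it
implements, the assumptions behind them, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. Shift prediction from bead geometry

### Model

A residue of a coarse-grained (CG) protein is described by one backbone
bead (BB) and up to four side-chain beads (SC1..SC4). Chemical shifts are
sensitive to local backbone conformation, which at bead resolution is
captured by five angles per residue *i*:

* bond angles centred on BB(i): β = ∠(BB(i−1), BB(i), BB(i+1)),
  α = ∠(SC1(i), BB(i), BB(i−1)), γ = ∠(SC1(i), BB(i), BB(i+1));
* dihedrals over the flanking backbone: θ₁ = dih(BB(i−2..i+1)),
  θ₂ = dih(BB(i−1..i+2)).

Each residue contributes a 32-value block — a 22-value amino-acid embedding
(BLOSUM62 rows, extended by two codes for oxidized cysteine CYO and
cis-proline PRC) plus sin/cos of the five angles — and the blocks of
residues *i−1, i, i+1* concatenate into a 96-value tripeptide feature
vector. Angles whose beads do not exist (chain ends, glycine without SC1)
contribute zero to *both* their sin and cos slots, which makes "missing"
representable and keeps the map total.

The network is deliberately small: 96 → 26 (ELU) → 6 (linear), predicting
the six backbone secondary shifts (N, C, CA, CB, H, HA) simultaneously.
Secondary shifts (observed minus random-coil) isolate the structural
signal; random-coil values enter only as an input table.

The exact triplet/quadruplet conventions above are one of several
reasonable readings of "angles between a residue's BB and its neighbours";
they are frozen by a feature-layout version tag
(`cgnmr-tripeptide-v1`) carried by both the featurizer and every weight
file, and a model refuses to run against a featurizer with a different tag.

### Differentiability

Every feature is a smooth function of bead coordinates away from
degenerate geometries, so the chain rule

d(pred)/d(x) = W_out · diag(ELU′) · W_hidden · d(sin,cos)/d(angle) ·
d(angle)/d(x)

gives an analytic Jacobian of the six predictions with respect to the
coordinates of every bead entering the features (BB(i−3..i+3),
SC1(i−1..i+1)). Angle gradients use the standard Kabsch-free forms; the
dihedral gradient follows Blondel & Karplus, sign-matched to the atan2
torsion convention (cis = 0, trans = π). Degenerate geometries (collinear
triples) raise rather than silently return zero — except where the masking
rules apply, in which case the masked slots contribute exactly zero
gradient. All gradients are validated against central finite differences
in the test suite.

### Training

Mean-squared-error loss over available (masked) targets, Adam at learning
rate 0.001, early stopping when the validation loss has not strictly
improved for `patience` consecutive epochs; the best-validation parameters
are returned. Structures never straddle the train/validation/test split.
Raw-shift outliers further than 3 reference SDs from the reference mean
are discarded before conversion to secondary shifts (strictly greater
than — a value at exactly 3 SD is kept).

Two choices the source protocol leaves open:

* **Targets are trained in raw ppm** without per-atom standardization, so
  the per-atom test RMSEs ε_a live directly in ppm and can be used as
  flat-bottom widths without conversion.
* **Batch size defaults to 64**, seeds for weight init and shuffling are
  part of the signature, and two runs with the same seed produce identical
  weights.

**Scaling note (desk-sized corpora).** The production protocol evaluates
early stopping once per epoch over a ~273k-sample corpus. On the 5k-sample
synthetic corpora used in the tests, one epoch is ~70× fewer parameter
updates, and with batch 64 / patience 5 the strict-improvement stop fires
on minibatch noise roughly 3× above the noise floor. The teacher–student
acceptance test therefore passes `batch_size = 200, patience = 100` —
keeping patience roughly constant *in units of updates* — rather than
altering any threshold. The defaults are unchanged.

## 2. Chemical-shift restraint

V_CS = K_CS Σₙ Σₐ (δCSₙₐ)², with the residual clipped to zero inside
±ε_a: the flat bottom prevents over-restraining within the model's own
error. The boundary uses strict inequalities (a residual exactly at ε_a is
inside). The clipped-square is C1 at the boundary, so forces are
continuous. K_CS multiplies squared ppm residuals; the ppm² factor is
absorbed so V_CS reads in kJ/mol.

K_CS is ramped from zero by `ramp_rate` (default 0.001) per integration
step to a plateau (25 kJ/mol is a sensible default; `scan_kcs` picks the
smallest candidate whose short-run shift RMSE ties the minimum, which
avoids over-restraining). The ramp is owned by the schedule (the force
provider), not by the potential.

## 3. NOE restraints

Atomistic NOE records are translated to bead pairs in three stages, all
driven by the r⁻⁶ distance dependence of the NOE signal:

1. **Mapping**: for an atom pair (aᵢ, aⱼ) with NOE distance d and beads
   (Aᵢ, Aⱼ), D = |(aᵢ−Aᵢ) + d·û(aᵢ→aⱼ) + (Aⱼ−aⱼ)| — walk bead→atom, the
   NOE distance along the interatomic direction, atom→bead.
2. **Condensation**: multiple atom pairs of one record mapping to the same
   bead pair combine as the r⁻⁶-weighted mean of their mapped distances.
3. **Aggregation**: distinct records on the same bead pair average
   arithmetically.

Bounds r₀/r₁/r₂ shift by the same additive bead-geometry offset
(D′ − d), preserving the flat-bottom width (the source is silent here; an
additive offset is the choice that keeps the experimental uncertainty
window intact). Missing bounds default to r₀ = 0 and r₂ = r₁ + 0.5 nm.
When several residue pairs contribute to one record, contributors whose
reference interatomic distance exceeds d + slack (slack default 0.2 nm,
configurable — the source says only "significantly larger") are dropped.

The potential is the Torda–van Gunsteren piecewise form: harmonic below
r₀, zero on [r₀, r₁), harmonic on [r₁, r₂), linear with constant slope
K(r₂−r₁) beyond r₂ (continuous and C1 at all knots). Restraints can act on
an exponentially time-averaged distance; the printed recursion has
typographically lost exponents, so the canonical r⁻³ running average

r̄(t) = [e^(−Δt/τ) r̄(t−Δt)⁻³ + (1−e^(−Δt/τ)) r(t)⁻³]^(−1/3), τ = 0.05 ps

is implemented, with r̄(0) = r. Force is applied only when r and r̄
violate the *same* bound. The printed linear-regime cap
min((r−r₁)(r̄−r₁), r₂−r₁) mixes nm² with nm; the default
(`cap_mode = "linear"`) caps the magnitude factor as min(r−r₁, r₂−r₁),
which reduces exactly to the instantaneous force in the memoryless limit
τ→0; `cap_mode = "product"` preserves the literal product. The force
constant ramps as K^t = K(1−e^(−t/τ_ramp)); τ_ramp defaults to τ but is
independently configurable, because τ = 0.05 ps makes the ramp
near-instant at dt = 10 fs.

## 4. Engine

Units nm/ps/u/kJ·mol⁻¹, k_B = 0.0083144621. Bead masses default to 72 u
(the common CG bead mass). A force provider is a closure returning
(energy, −∇energy); the contract is enforced by finite-difference tests.
The toy force field — harmonic BB–BB bonds (b₀ = 0.35 nm, k = 5000),
harmonic BB–BB–BB angles (127°, k = 25), BB–SC1 bonds at their input
lengths, and a purely repulsive harmonic excluded volume (σ = 0.4 nm) — is
a desk-scale stand-in for a production CG force field: it keeps chains
connected and self-avoiding and nothing more.

Integration is BAOAB Langevin (the O-block is the exact
Ornstein–Uhlenbeck update), chosen for configurational accuracy at
dt = 10 fs; default friction 0.01 ps⁻¹. Minimization is steepest descent
with an adaptive step. NVT only; no periodic boundaries by default (toy
systems are small).

## 5. Ensemble metrics — conventions

* **RMSD/RMSF**: Kabsch superposition on a caller-supplied selection
  ("structured regions" are the caller's responsibility); RMSF may align
  on a different selection than it reports (`align`), so a single
  oscillating bead is measurable without superposition leakage.
* **S-matrix**: fixed 0.1 nm bins over [0, joint max + 0.1] shared by both
  ensembles (bin width is not printed in the source); breaks not covering
  the data are an error rather than silently clipped.
* **τ/ω**: implemented exactly as printed, including
  h_bundle = mean(start) − mean(end), which is *antiparallel* to the
  individual helix vectors h_TM = end − start; a single ideal helix
  therefore has ω = 180°. Callers comparing to tilt conventions elsewhere
  should be aware of the orientation.
* **Free energy**: F_i = −k_B T ln H_i on normalized densities; empty bins
  are masked (NA), never ±Inf; σ_i = k_B T · (1/mean H) ·
  sqrt((mean H² − (mean H)²)/(N−1)) over N bootstrap histograms (a
  standard-error-of-the-mean reading of the printed formula; a degenerate
  sample gives exactly 0).
* **Contact lifetimes**: transition-based with hysteresis (open below
  r₀ = 0.8 nm, close above r₁ = 1.0 nm); contacts open at the trajectory
  end are censored and excluded from means, as are pairs that never form.
* **Diffusion**: 3-D MSD slope/6 over the 100–500 ps window, Pearson r
  reported; a log–log exponent > 1.5 flags superdiffusive beads, so a
  ballistic fit with r ≈ 1 is not mistaken for diffusion.
* **Radial profile**: the printed θ = π/2 "proportion of circular area" is
  dimensionally inconsistent; it is replaced by a configurable excluded
  area fraction f ∈ [0, 1) (default 0.5).
* **Twist**: dihedral hinged on the fibril axis — (a2, a1, b1, b2) for
  layer beads (a1, a2), (b1, b2) — so translated layers read 0 and axially
  rotated layers read the rotation angle.
* **ADF**: no unit-root package is available in the target environment, so
  the augmented Dickey–Fuller regression (constant, no trend;
  lag = ⌊(n−1)^⅓⌋) is run with `stats::lm` and the t-statistic is mapped
  to a p-value by interpolating the asymptotic Dickey–Fuller quantiles,
  clamped to [0.01, 0.99].

## 6. Synthetic data: what a green test establishes

The generators produce self-avoiding bead chains (0.35 nm BB spacing,
>0.25 nm separation), teacher-network shift tables (frozen random
96-26-6 network + Gaussian noise) and NOE tables whose d is the target's
own bead distance, so the target satisfies every restraint exactly and is
a global minimum of V_CS + V_NOE — by construction, suitable for
energy/force/steering tests. They are pure functions of their seeds.

What they do **not** emulate: real secondary-structure statistics, real
shift–structure correlations (the teacher is random, not physical),
experimental NOE ambiguity/calibration error, solvent and membrane
environments, or the production CG force field. A green steering test
establishes that the restraint machinery transmits correct forces and that
restrained dynamics recovers a restraint-consistent conformation on a toy
landscape — not that the method reaches the published accuracy on real
proteins.

Fixture choices in the end-to-end steering test (criterion 6): the start
is the target perturbed by 0.15 nm Gaussian noise (a partially unfolded
state, mirroring the refolding demonstration the protocol was designed
for); the toy angle term is softened (k = 5) because secondary-structure
terms are removed when NMR restraints are applied; NOEs are two-sided
("exact NOEs"); friction is 2 ps⁻¹ so a 20 ps run is overdamped and
relaxes; and RMSD is measured over BB beads, the convention in which
backbone RMSD is defined for bead models. The unrestrained arm differs
only in having no restraint providers.

## 7. Known limitations

* The shift model is an architecture + training procedure; shipped
  accuracy claims would require the external structure/shift corpus, which
  is out of scope. ε_a is always recomputed from a held-out set or
  supplied by configuration.
* The engine is a teaching-scale NVT integrator: no PBC by default, no
  barostat, no electrostatics, no solvent; it is not a substitute for a
  production MD package.
* Replica-averaged (ensemble) chemical-shift restraints and orientational
  restraints (RDC/CSA) are not implemented.
* The ADF p-value is asymptotic and interpolated; for publication-grade
  inference use a dedicated econometrics package.
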