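---
title: "Methods: CD spectrum deconvolution, model training, and the companion tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CD spectrum deconvolution, model training, and the companion tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsk)
```

## The problem

Far-UV circular dichroism (CD) reports on the secondary-structure content
of a protein in solution, but extracting fractions from a spectrum is an
ill-posed inverse problem, historically hardest for β-sheet proteins:
β-strand spectra vary continuously with the sheet's sense
(parallel/antiparallel) and twist.  `cdsk` addresses this by resolving
eight components — regular mid-helix (`Helix1`), distorted helix ends
(`Helix2`), antiparallel sheet in three twist classes (`Anti1` left-hand,
`Anti2` relaxed, `Anti3` right-hand twisted), parallel sheet, turn, and
everything else (`Others`) — and by letting the effective basis spectra
depend on where the protein sits in composition space.

## The quadratic spectral model

A classic deconvolution writes the spectrum as a fixed linear combination
`CD(λ) = Σ_i b_i(λ) ss_i` of one basis spectrum per component.  `cdsk`'s
central model generalizes this: at each wavelength an 8 × 8 basis matrix
`M_λ` gives

    CD(λ) = ss' M_λ ss,

so each component's effective basis spectrum,
`b_i(ss, λ) = (M_λ ss)_i`, is itself a linear function of the overall
composition.  Because the fractions sum to one, a *constant-column*
matrix set (column `i` equal to `b_i·1`) makes the quadratic form
collapse exactly to the classic linear model; the linear model is thus a
special case, used throughout as the baseline and as an oracle in tests.
Only the symmetric part of `M_λ` affects the quadratic form; matrices are
stored as trained and symmetrized on evaluation.

### Solving the inverse problem

Estimating the composition requires minimizing
`½‖ss'Mss − CD_exp‖²` over the probability simplex — a quartic,
non-convex objective.  The solver alternates two steps:

1. form the effective basis `B[λ, i] = (M_λ ss)_i` at the current
   composition and solve the *simplex-constrained linear* subproblem
   `min ‖B z − CD‖²`, and
2. move along the segment `ss + t(z − ss)` (which stays on the simplex)
   with an exact line search: the objective restricted to the segment is
   a quartic in `t`, so its stationary points are roots of a cubic and
   the best `t ∈ [0, 1]` is found in closed form.

The line search makes the iteration monotone by construction — the
alternating step alone does not guarantee descent of the true quartic —
and the iteration stops when the relative objective decrease falls below
`1e-10` (at most 200 iterations).  Because the objective is non-convex,
the solver restarts from the 8 simplex vertices plus 12 seeded
Dirichlet(1) draws (20 starts by default) and keeps the lowest objective,
breaking ties by the lowest start index so results are reproducible.

The simplex-constrained linear subproblem is solved exactly by an
active-set method (C++/Armadillo) that keeps the equality constraint
inside every KKT system.  Degenerate vertices can make active-set methods
cycle between releasing and re-pinning zero-weight coordinates; the
solver tracks its best iterate and stops when the quadratic objective no
longer improves.  Tests compare it against an exhaustive
support-enumeration oracle (every face of the simplex, 255 candidate
supports) to 1e-6.

## Training the basis matrices

Training data are pairs of known compositions and spectra on a shared
1 nm grid.  Two least-squares problems define the procedure:

* per wavelength, the linear system `SS_ref · b_λ ≈ CD_ref,λ` gives the
  best fixed basis values on any chosen subset of reference proteins
  (rank-deficient subsets are solved minimum-norm and flagged);
* per component and wavelength, a regression of subset basis values
  `b_{i,λ}` on subset mean compositions yields column `i` of `M_λ`.

The link between the two — which subsets, and how their solutions are
paired with compositions — is genuinely open, and is the central design
decision of this package.  `cdsk` uses two subset families:

1. **Greedy leave-out traces.**  Starting from the full set, the protein
   whose removal most improves the component's recovery (re-estimating
   *every* reference protein with the subset's constant-column model) is
   removed, until no removal improves or a cap (default 12) is reached.
   The improvement criterion does not involve the wavelength, so one
   trace per component serves the whole grid.  These traces identify
   atypical spectrum/composition pairs, but their subset means move very
   little (spread ≈ 0.01 in composition), so on their own they cannot
   identify an 8-parameter composition dependence.
2. **Composition-stratified subsets.**  For each component the reference
   proteins are ordered by that component and cut into tertiles (minimum
   9 proteins per stratum).  These subsets span the composition space
   widely and give the regression its leverage.

The per-component regression is ridge-stabilized, with the penalty
*centred on the constant-column solution* rather than on zero: when the
data carry no composition signal the column degenerates gracefully to
the baseline model instead of shrinking the basis spectra away.  The
ridge weight is chosen per component from a small grid by two-fold
cross-validation (deterministic odd/even folds in id order) of the
full-set spectrum reconstruction error, and a trained column is accepted
only if it beats the constant column in *every* fold by at least 1%.
Finally a joint "do no harm" screen re-estimates the cross-validated
compositions under the assembled model and rejects the trained columns
altogether if any component's recovery degrades.  The result is a
conservative estimator: with little data (n ≈ 30–50 in our synthetic
experiments) it returns exactly the constant-column model; with more
data (n ≈ 100) it captures the composition dependence and improves
every component's held-out recovery.

Training uses no randomness; ties break by id order, and the reference
set is sorted by id on construction, so training is invariant to entry
order and byte-identical across runs.

## Spectrum processing conventions

* **Units.**  Internal unit is Δε (M⁻¹cm⁻¹ per mean residue);
  `[θ]_MRE = 3298·Δε` and `θ_mdeg = 32980·c(M)·l(cm)·N_res·Δε`.
  Conversions are exactly invertible.
* **Smoothing** (default 2 nm window) averages points strictly inside
  the window; boundary points are excluded, so data already at 1 nm
  pitch pass through unchanged and noise-free spectra are not distorted.
  Edge points average over the truncated window rather than inventing
  data outside the measured range.
* **Regridding** to 1 nm uses bin averages (±0.5 nm, inclusive), not
  interpolation.  Smoothing happens on the native grid first.
* **Fit metrics.**  RMSD compares the *raw* spectrum to the fit
  (sensitive to noise); NRMSD compares the *smoothed* spectrum to the
  fit, normalized by the smoothed spectrum's norm (reflects structural
  fit quality).  Conventional fit ranges are 175–250, 190–250 and
  200–250 nm, with the lower limit movable in 5 nm steps.
* **Amplitude checks.**  A maximum |Δε| outside [0.1, 40] triggers a
  warning (wrong units or normalization), and `scale_scan()` refits over
  factors 0.5×–2× (31 log-uniform steps) to locate amplitude errors.

## Secondary structure from 3D structures

The per-residue assignment follows the hydrogen-bond dictionary
approach: the amide H is rebuilt 1 Å from N along the preceding C=O
direction, H-bonds use the electrostatic criterion
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol`,
n-turns give helices (two consecutive i→i+4 turns) and turns, and
bridge patterns give parallel/antiparallel ladders.  Strand beats helix
when both patterns apply.  3₁₀/π helices and isolated bridges map to
`Others` by default (both mappings configurable).

Helices split into `Helix2` (two residues at each end) and `Helix1`
(middle): a run of length L ≥ 5 gives L−4 `Helix1`; shorter runs are all
`Helix2`.

Antiparallel strand residues get a signed twist angle: the dihedral
between the `CA(i−1)→CA(i+1)` chain vectors of the residue and its
bridge partner, measured about the inter-strand axis, right-hand twist
positive (the partner vector is reversed first for antiparallel
ladders).  Default bins are `< 3°` → `Anti1`, `3–23°` → `Anti2`,
`≥ 23°` → `Anti3`; both thresholds and the bridge/3₁₀ mappings are
arguments, since the angle convention and cut-offs are implementation
choices.  Strand-terminal residues inherit their ladder's mean twist.

PDB files are parsed with `bio3d`; mmCIF files use a small internal
`atom_site` reader.  Both keep the first model, altloc `A`/blank, and
backbone-complete amino-acid residues only.

## Synthetic data generators

All generators are pure functions of their arguments; randomness flows
through a private seeded stream that never disturbs the caller's RNG.

* **Ground-truth models** build each component's basis spectrum from 2–3
  Gaussian bands (centers ≤ 235 nm, widths 5–15 nm, amplitudes 2–9 in
  |Δε|, signed), plus symmetric Gaussian coupling terms scaled by a
  `coupling` factor (default 0.15; 0 gives an exactly constant-column
  model).  Component spectra are constrained to pairwise cosine
  similarity ≤ 0.8 (redrawn deterministically otherwise): the eight
  components exist precisely because their spectral signatures differ,
  and unconstrained draws occasionally produce near-duplicate spectra
  that would make the synthetic inverse problem unidentifiable in a way
  the modeled system is not.
* **Reference sets** draw compositions from Dirichlet(0.8) — spreading
  mass toward the simplex corners so helix-rich, β-rich and
  disordered-like proteins all occur — and add Gaussian noise with
  σ = 1% of each clean spectrum's peak |CD| by default.
* **Structures** are built from ideal internal coordinates (helix
  φ = −57°, ψ = −47°; strands φ = −139°, ψ = 135°).  Sheet partners are
  placed by a deterministic grid search maximizing inter-strand
  hydrogen bonds (antiparallel partners are the C2 image about the
  inter-strand axis).  An imposed twist applies a helicoid map about the
  ribbon's central axis with one measurement-based correction step, so
  the requested and measured twists agree to ≈ 1–2°.  The map preserves
  inter-strand H-bond geometry exactly (partners sit at matching
  positions along the axis) at the cost of slight covalent shear at
  large twist; the ideal-bond-length guarantee therefore applies to
  untwisted fixtures.
* **Fold databases** build a 2×2×2×2 class/architecture/topology/
  homology hierarchy with hierarchically perturbed centroids, and
  **disorder references** draw the two classes inside separated cones in
  triplet space with random positive amplitudes (only the direction
  separates the classes, matching the cosine metric's scale
  invariance).
* **Melting curves** evaluate the two-state model and add noise scaled
  to the transition amplitude.

What passing tests on these generators shows — and what it does not:
recovery, training-benefit and classification results demonstrate the
*algorithms* are correct and well-behaved under controlled conditions.
Synthetic spectra contain no aromatic side-chain contributions,
scattering artifacts, linear dichroism, baseline drifts or wavelength-
dependent noise, and the synthetic fold space is far smaller than a real
domain classification; accuracy numbers on synthetic data therefore do
not predict accuracy on experimental spectra.

## Thermal denaturation

The two-state model with linear baselines is

    CD(T) = [(A_N + m_N T) + (A_D + m_D T)·K(T)] / [1 + K(T)],
    K(T)  = exp(y)·(T/T_m)^(ΔC_p/R),
    y     = (1/R)·[(T_m ΔC_p − ΔH_m)/T + ΔH_m/T_m − ΔC_p],

with `A_N, A_D` the baseline intercepts at 0 K, `m_N, m_D` their slopes,
`T_m` the melting temperature and `ΔH_m` the unfolding enthalpy at
`T_m`; `ΔC_p` is fixed, not fitted (≈ 50 J/(mol·K) per residue for small
globular proteins, see `estimate_dcp()`).  The curve is evaluated in log
space (`K/(1+K)` via the logistic function), so extreme arguments cannot
overflow.  Stability at any temperature follows from

    ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p[(T_m − T) + T·ln(T/T_m)],

which satisfies `ΔG(T_m) = 0` identically and agrees with `−RT ln K` of
the model's equilibrium factor — both identities are asserted in tests.

Fitting is Levenberg–Marquardt over six parameters.  Initialization is
automatic: baselines from lines through the coolest and hottest 20% of
points, `T_m` from the half-transition crossing of the
baseline-normalized signal, `ΔH_m` from a van't Hoff slope over the
transition region; any value can be overridden for manual re-fits.
Standard errors come from the linearized covariance `s²(JᵀJ)⁻¹`,
inverted on a rescaled system because the parameter magnitudes span nine
orders.  Data that a single straight line explains to within the
point-to-point noise are flagged `no_transition` and the fit is marked
non-converged.  In simulation (0.5 K pitch, 293–363 K, 1% noise), the
RMS recovery error is ≈ 0.04 K for `T_m` and ≈ 1.5% for `ΔH_m` over 200
curves; individual draws can exceed twice the RMS, as expected for a
noise-limited estimator.

## Fold recognition and disorder classification

Proteins live as points in the 8-dimensional composition space.  Three
search modes over a labeled database: `closest_k()` (Euclidean, ties by
id), `radius_search()` (an axis-aligned box by default — "within the
expected error in *each* component" — with a Euclidean-ball option), and
`wknn_predict()` (kernel `1/(d + 1e-9)`, pluggable) which sums neighbor
weights per label prefix at each of the four hierarchy levels.  Chain
length is metadata and never enters a distance.  Disorder classification
reduces a spectrum to one of the canonical wavelength triplets
(197-206-233 or 212-217-225 nm) and takes a majority vote of the 10
nearest references under the cosine distance; ties resolve
conservatively to "disordered" and are flagged.

## Extinction coefficients

`epsilon_at()` implements the additive far-UV schemes at 214 nm
(Kuipers & Gruppen 2007) and 205 nm (Anthis & Clore 2013): per-residue
contributions, one peptide-bond term per bond, and a net per-disulfide
adjustment (−560 M⁻¹cm⁻¹ at 205 nm; no cystine term is tabulated at
214 nm, so 0).  The coefficients ship as commented CSV constants files
under `inst/extdata/`, not as magic numbers; terminal corrections are
not applied.  Nonstandard letters (B, J, O, U, X, Z) are rejected with
their positions.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: 100 random instances
for solver/model oracles, 50 synthetic proteins for recovery, reference
sets of n = 30/50/100 with a 120-spectrum held-out set for the training
benchmark, 200 simulated melting curves, ~1000-record fold databases,
and a 262-record disorder reference — sizes at which every experiment
rests on hundreds of independent fits while the full suite runs in a
few minutes.  Every stochastic step is seeded; seeded pipelines
(synthesis, training, multi-start fitting) are byte-identical across
runs, which the test suite asserts on written files.

## Known limitations

* The eight components do not cover polyproline-II helices, specific
  turn types, or 3₁₀-helices; aromatic contributions are ignored.
* Training needs roughly n ≥ 100 reference proteins before the
  composition-dependent model separates from the constant-column
  baseline; below that it intentionally returns the baseline.
* The structure module assigns from backbone geometry only; it does not
  read author-supplied secondary-structure records, and very short
  chains (< 4 residues) are all `Others`.
* The two-state thermal fit assumes a reversible, two-state transition;
  multi-state or irreversible unfolding violates the model silently.
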