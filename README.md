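# cdsk — circular dichroism structure kit

`cdsk` is an R toolkit for analyzing protein far-UV circular dichroism
(CD) spectra and the measurements that usually accompany them.  It is
aimed at structural biologists and protein scientists who use CD to
verify folding, quantify secondary structure (especially in
β-sheet-rich systems such as antibodies, amyloids and membrane
proteins), follow thermal unfolding, and cross-check experimental
spectra against 3D structures or structure predictions.

## What it computes

The core quantity is the eight-component secondary-structure vector

    ss = (Helix1, Helix2, Anti1, Anti2, Anti3, Parallel, Turn, Others),

where the helix splits into regular middle (`Helix1`) and distorted ends
(`Helix2`), and antiparallel β-sheet splits by twist: left-hand twisted
(`Anti1`), relaxed (`Anti2`) and right-hand twisted (`Anti3`).  The
spectral model is quadratic in the composition,

    CD(λ) = ssᵀ · M_λ · ss,     Σᵢ ssᵢ = 1,  ssᵢ ≥ 0,

with an 8×8 basis matrix `M_λ` per wavelength, so each component's
effective basis spectrum depends on where the protein sits in
composition space; a constant-column `M` reduces exactly to the classic
fixed-basis linear model.  The package provides:

* **Deconvolution** — `fit_secondary_structure()` solves the
  simplex-constrained quartic inverse problem by a monotone alternating
  scheme with multi-start (Rcpp/Armadillo active-set core), plus
  spectrum I/O, unit conversion (Δε, mean-residue ellipticity, mdeg),
  2 nm smoothing, 1 nm regridding, RMSD/NRMSD fit metrics and an
  amplitude-rescaling scan.
* **Training** — `train_basis_matrices()` estimates `M_λ` from a
  reference set of proteins with known structures via per-wavelength
  least squares on subset families (greedy leave-out traces plus
  composition-stratified subsets) with cross-validated, conservatively
  accepted ridge regression; `constant_column_model()` is the baseline.
* **Structure module** — `read_structure()` (PDB/mmCIF) and
  `ss_composition()` compute the same eight components from 3D
  coordinates via a hydrogen-bond-based assignment (Kabsch–Sander-style
  energies, helix split, β-sense and per-residue twist binning).
* **Fold recognition** — `closest_k()`, `radius_search()` and
  `wknn_predict()` search a fold database in the 8-D composition space
  across a four-level class/architecture/topology/homology hierarchy.
* **Disorder classification** — `classify_disorder()` votes among the
  10 cosine-nearest references on a CD wavelength triplet
  (197-206-233 or 212-217-225 nm).
* **Thermal stability** — `fit_melting()` fits the two-state
  Gibbs–Helmholtz model (fixed ΔC_p) to temperature scans and reports
  `T_m`, `ΔH_m` and ΔG at 25/37 °C.
* **Extinction coefficients** — `epsilon_at()` at 214 and 205 nm from
  sequence and disulfide count.
* **Synthetic data** — seeded generators (`gen_basis_truth()`,
  `gen_reference_set()`, `gen_structure()`, `gen_melting_curve()`,
  `gen_fold_db()`, `gen_disorder_ref()`) for every input the suite
  needs.

All user-facing functions take a data frame (tibble) first and return
tibbles or objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Deconvolve a synthetic spectrum generated from a known model and
composition:

```r
library(cdsk)
truth <- gen_basis_truth(seed = 1)                 # ground-truth model
ref   <- gen_reference_set(3, truth, sigma = 0.01, seed = 2)
s     <- cd_spectrum(ref$wavelength, ref$cd[1, ])  # one noisy spectrum
res   <- run_single(s, truth, seed = 1)
res$fit
#> <cd_deconv> fit on 175-250 nm, RMSD 0.01319, NRMSD 0.01654
#>   Helix1   Helix2    Anti1    Anti2    Anti3 Parallel     Turn   Others
#>   0.0290   0.0990   0.0715   0.0552   0.1187   0.2109   0.1074   0.3082
res$groups
#>   group        fraction
#> 1 Helix           0.128
#> 2 Antiparallel    0.245
#> 3 Beta            0.456
#> 4 Turn+Others     0.416
```

The estimated fractions recover the generating composition (0.0332,
0.0996, 0.0731, 0.0571, 0.1158, 0.2105, 0.1043, 0.3064) to within about
0.004 per component at 1% noise; RMSD is the raw-data misfit and NRMSD
the (dimensionless) misfit of the smoothed spectrum.

A thermal scan, and the same eight components from a structure:

```r
p <- list(A_N = -11, m_N = 0.004, A_D = -2, m_D = 0.0015,
          T_m = 330, dH_m = 4e5, dCp = 8000)
fit_melting(gen_melting_curve(p, sigma = 0.01, seed = 3), dCp = 8000)
#> <thermal_fit> T_m = 329.98 K (56.83 C), dH_m = 401 kJ/mol, dCp = 8 kJ/(mol K)
#>   dG(25C) = 26 kJ/mol, dG(37C) = 19.2 kJ/mol, RMSD = 0.07093

ss_composition(gen_structure("helix", 20))$ss
#>   Helix1   Helix2    Anti1    Anti2    Anti3 Parallel     Turn   Others
#>      0.7      0.2      0.0      0.0      0.0      0.0      0.0      0.1
```

`T_m` and `ΔH_m` are recovered within 0.02 K and 0.3% here; the ideal
20-residue helix assigns 18 helical residues, split 14 middle + 4 ends.

A command-line front end over the same functions ships in
`inst/cli/cdsk` (subcommands `fit`, `train`, `pdb2ss`, `fold`,
`disorder`, `melt`, `epsilon`, `synth`).

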