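# ilerot

Isoleucine side-chain rotamer geometry, statistics and steric scanning.

## The problem

Isoleucine has two side-chain torsion angles, χ1 (N–CA–CB–CG1) and χ2
(CA–CB–CG1–CD1).  Because each prefers the three staggered states g+
(~60°), t (~180°) and g− (~300°), the (χ1, χ2) plane splits into nine
120° × 120° *rotamer sections* that are very unevenly populated: more
than half of all isoleucines in crystal structures sit in section 6
(χ1 g−, χ2 t).  The angles actually deposited in the PDB are not pure
observations — at low resolution the restraint targets of the refinement
program pull torsions toward program-specific ideals, so observed means
drift with resolution, secondary structure and software.  Quantifying
that drift, and locating the true steric optima of the side chain in
helix and strand environments, is what this package is for.  Its users
are structural bioinformaticians and refinement-software developers who
need section-resolved torsion statistics and a reproducible steric
baseline.

## What the package provides

* **Structure input and filtering** — `parse_pdb()` (ATOM records via
  bio3d, header metadata: resolution, refinement programs, method,
  year), `read_dssp()`, `extract_ile_observations()` and
  `apply_filters()` with the standard quality criteria: X-ray only, no
  (peri-)terminal residues, no Gly/Pro/noncanonical neighbours, complete
  atoms, every backbone/CB B factor `< 60 Å²` *or* `< 2.5 ×` the chain
  Cα average, secondary structure in {H, E, L}, geometric sanity.
* **Rotamer statistics** — `section_of()`, `histogram2d()` (1° bins,
  log-scaled render), `fraction_by_resolution()` (0.1 Å bins),
  `mean_angle_by_resolution()` (0.2 Å bins, ≥ 50 observations per dot,
  mean ± SEM) and `fit_section_gaussian()` for per-section 2D Gaussian
  optima and spreads.
* **Idealized hosts and the steric scan** — `build_ideal_secondary()`
  constructs a polyalanine α-helix (φ,ψ = −57,−47; 11 residues) or
  β-hairpin (14 residues, Gly turn) with one central isoleucine;
  `scan_chi_grid()` rotates the side chain through all 360² = 129 600
  (χ1, χ2) combinations in 1° steps under a documented soft-sphere
  steric field, recording the energy, the atom feeling the greatest
  force, and the minimum van-der-Waals-corrected contact
  (pseudo-atoms QG/MG/MD at 2.00 Å, H 1.20, C 1.60, N 1.50, O 1.45 Å).
  `find_optimum()` refines the grid argmin to 0.05°.
* **Synthetic data with ground truth** — `synthetic_spec()` /
  `generate_dataset()` emit PDB files with known per-section rotamer
  distributions, resolution and program labels, planted quality
  violations, and a resolution-dependent bias
  `observed = true + λ(res)·wrap(target − true)` that is zero at atomic
  resolution, so every pipeline stage is testable without external data.

## Worked example

Generate a 500-isoleucine synthetic archive, extract and filter the
observations, and look at section populations and the section-6 optimum:

```r
library(ilerot)
spec <- synthetic_spec(n_ile = 500)
gen  <- generate_dataset(spec, seed = 1)
obs  <- do.call(rbind, lapply(gen$structures, extract_ile_observations))
res  <- apply_filters(obs)

round(100 * table(factor(res$observations$section, levels = 1:9)) /
        nrow(res$observations), 1)
#>    1    2    3    4    5    6    7    8    9
#>  0.6  0.8  6.2 10.2 11.6 49.8  2.6 11.4  6.8

mean_angle_by_resolution(res$observations[res$observations$section == 6, ],
                         "chi1", group_vars = "section", bin = 0.5)
#>   section res_bin  n  mean    sem
#> 1       6    1.25 62 293.7 0.9327
#> 2       6    1.75 90 292.8 0.6728
#> 3       6    2.25 55 293.4 0.6592

f <- fit_section_gaussian(histogram2d(res$observations), 6)
#> section 6 optimum: chi1 292.6 chi2 162.2 (sigma 5.7, 6.2)
```

Half of the observations fall in section 6, the binned χ1 means recover
the generating mean of 293° within their standard errors at every
resolution, and the 2D Gaussian fit localizes the section-6 optimum at
(292.6°, 162.2°).

The steric scan of the idealized helix:

```r
helix <- build_ideal_secondary("helix")
scan  <- scan_chi_grid(helix, step = 1)     # 129 600 conformations, ~25 s
find_optimum(scan)
#>     chi1     chi2
#> 291.6250 164.3125
```

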