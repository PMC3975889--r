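---
title: "Methods: isoleucine rotamer statistics and the chi1/chi2 steric scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoleucine rotamer statistics and the chi1/chi2 steric scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and numerical
choices behind its three layers: the observation pipeline (structures in,
filtered isoleucine torsions out), the section-resolved statistics, and
the exhaustive steric scan of idealized secondary-structure hosts.

## 1. Observations and quality filtering

An isoleucine observation is the tuple (χ1, χ2, φ, ψ, secondary
structure, resolution, refinement program, year).  χ1 is the
N–CA–CB–CG1 torsion and χ2 the CA–CB–CG1–CD1 torsion, both reported in
[0, 360) so the staggered classes are g+ ≈ 60°, t ≈ 180°, g− ≈ 300°;
φ and ψ are reported in (−180, 180].  Torsions use the standard sign
convention (cross-check against bio3d's `torsion.xyz` is part of the
test suite's oracle set).

Filtering mirrors standard crystallographic practice:

* X-ray entries only (the method string must begin with "X-RAY").
* No terminal residues, none adjacent to a terminus, and no Gly, Pro or
  noncanonical (including HETATM-coded) neighbour — all of these distort
  the local backbone that the statistics condition on.
* All eight heavy atoms present.
* Every backbone/CB B factor below 60 Å² **or** below 2.5 × the
  chain-average Cα B factor.  The average is per *chain*, not per
  structure: B-factor scales can differ between chains of one entry.
* Secondary structure in {H, E, L}.
* Geometric sanity replaces an external residual-quality report: bond
  lengths within 0.2 Å of ideal and no non-bonded contact below 1.5 Å in
  the residue's immediate neighbourhood.  This catches corrupt
  coordinates, not subtle refinement pathology.

Rejection is data, not error: `apply_filters()` returns an audit table
with one reason per rejected residue, and the result is independent of
input order.  Alternate locations keep the conformer with the highest
summed occupancy (ties broken by altloc letter); occupancy itself is
recorded and only filtered when `occupancy_min` is set, since the main
analysis conditions on B factors instead.

Secondary structure comes from a DSSP file when one is supplied,
otherwise from the builtin assigner: Kabsch–Sander hydrogen-bond energy
`E = 0.084·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332 kcal/mol` with a
−0.5 kcal/mol cutoff, the amide H rebuilt 1.0 Å from N opposite the
preceding carbonyl, helix on runs of two consecutive i→i+4 turns, strand
on parallel/antiparallel bridges, and the 8-state alphabet collapsed to
H/E/L.  Loop residues are subclassified by φ,ψ windows (helical:
φ ∈ [−100,−30], ψ ∈ [−80,−5]; strand: φ ∈ [−180,−45],
ψ ∈ [85,180] ∪ [−180,−170]) into L-α, L-β and L-other.  The exact window
boundaries are not critical and are exposed as configuration; the strict
mode additionally drops helix/strand residues whose backbone torsions
disagree with their assignment.

## 2. Sections and statistics

The nine sections tile [0,360)² with half-open 120° cells; membership at
0/120/240 belongs to the lower edge (the data density at the exact
boundaries is negligible, but a convention is needed and this one is
encoded in a single table).  Numbering is row-major with χ1 columns
(g+, t, g−) and χ2 rows from g− (top) to g+ (bottom), so section 6 is
(χ1 g−, χ2 t) and section 9 is (g−, g+).

Binned statistics follow the conventions of resolution-stratified
torsion plots: population fractions in 0.1 Å resolution bins, binned
means in 0.2 Å bins, and every emitted dot backed by at least 50
observations (`min_count`, configurable).  Means are plain means in the
section frame rather than full circular statistics: a section spans a
contiguous 120° interval of [0, 360) that never crosses the 0/360 seam,
and observed spreads (σ ≈ 8°) are far below the 60° half-width, so the
circular correction would be orders of magnitude below the SEM.

Per-section optima come from a nonlinear least-squares fit
(Levenberg–Marquardt via minpack.lm) of
`background + amplitude·exp(−q/2)` to the 1°-binned counts of one
section, with `q` the correlated quadratic form in (χ1−μ1, χ2−μ2).
Starting values are the background-subtracted weighted centroid and
second moments; bounds keep μ inside the section, σ ∈ [0.5, 120]° and
|ρ| ≤ 0.95.  A fit is flagged unconverged when the optimizer fails *or*
the fitted amplitude does not exceed three times the Poisson noise scale
of the background (`3·sqrt(bg+1)`) — a flat section otherwise "converges"
to a meaningless peak.  Flagged fits fall back to the centroid.

## 3. Idealized hosts

The scan needs a helix and a strand environment.  Rather than carving
fragments out of deposited structures, the builders construct them from
Engh–Huber-style internal coordinates (N–CA 1.458, CA–C 1.525, C–N
1.329 Å; N–CA–C 111.2°, ω = 180°), with all hydrogens placed by standard
covalent geometry and staggered methyl protons.

* **Helix**: 11 alanines at φ,ψ = (−57, −47), isoleucine at position 6.
* **Hairpin**: 14 residues, two strands joined by a two-residue turn
  whose first residue is glycine, isoleucine at position 11.  Perfectly
  uniform strand torsions at (−139, 135) leave the two strands without
  an inter-strand hydrogen-bond ladder (only the rung next to the turn
  pairs), because ideal straight strands cannot satisfy several rungs at
  once.  The builder therefore carries backbone torsions that were
  calibrated once, numerically, by maximizing the Kabsch–Sander ladder
  energy of the three antiparallel rungs (6–9, 4–11, 2–13) under a
  clash penalty while pulling the strand torsions toward the ideal
  values; the strand residues deviate by ≲ 3° from (−139, 135) and the
  builtin assigner then labels both strand cores E.  The calibrated
  values are frozen in the code; passing explicit `phi`/`psi` or another
  length falls back to the uniform ideal plus a type-I′ turn.

The central isoleucine starts at χ1 = χ2 = 0 and is posed by rigid
rotations about CA–CB and CB–CG1; only atoms distal to the rotated bond
move, so bond lengths and angles are exactly conserved and
`set_side_chain()` followed by `measure_torsions()` is the identity to
10⁻⁶ degrees.

## 4. The steric field and the scan

The published scan used a full molecular-mechanics force field that is
not reproducible from printed information; this package substitutes a
deliberately simple, fully documented steric field:

* **Repulsion** `w·max(0, r_i + r_j − d)^k` per non-bonded pair (1–2 and
  1–3 excluded), with w = 100 model units/Ų and k = 2 — a smooth,
  harmonic-like overlap penalty.  Pairs closer than 0.1 Å contribute a
  finite capped term.
* **Attraction** −w_att·exp(−(d − r_sum)²/2s²) with w_att = 1 and
  s = 0.75 Å: a smooth reward for packing at the van der Waals contact
  distance, giving the surface genuine minima instead of flat
  zero-repulsion plateaus.
* **Intra-side-chain scale** 0.25 on pairs internal to the isoleucine
  side chain.  With frozen staggered methyl protons, rigid spheres
  overstate intra-rotamer H···H overlaps (real methyls counter-rotate by
  a few degrees); the scale is the same device as force-field 1–4
  scaling.
* **Torsion term** h/2·(1 + cos 3χ) on χ1 and χ2 with h = 10 model
  units: the intrinsic sp³ staggering preference, which a sphere model
  with frozen rotors underestimates.
* Nonbonded cutoff 20 Å (irrelevant at these motif sizes, kept
  configurable).

The four parameters beyond the radii were calibrated during field design
so that the scan optima of the two idealized hosts fall inside the
rotamer wells observed for helix and strand isoleucines; the acceptance
band for those optima is deliberately a well-membership band (±15°)
because a replacement field cannot be expected to agree to the degree.
The relative-depth properties asserted in the tests (sections 1/2 far
above section 6 in the helix; section 9 deeper in the strand than in the
helix) are *not* calibration targets — they follow from the geometry.

The scan objective sums all pairs involving at least one moving
side-chain atom plus the torsion term; static–static pairs are constant
during a scan and are omitted, so energies are side-chain interaction
energies (comparisons between motifs compare like with like).  The
whole-chain `steric_energy()` keeps every pair and returns analytic
per-atom forces, verified against central finite differences.

The 1° scan evaluates all 129 600 conformations exactly (no sampling) by
exploiting the rigid-rotation structure: intra-side-chain distances
depend only on χ2, the χ1-group/environment distances only on χ1, and
the χ2-group coordinates are a rotation of a precomputed stack, so each
χ1 row is a handful of vectorized matrix operations.  Per conformation
the scan stores the energy, the atom with the largest total force, the
minimum van-der-Waals-corrected distance from the QG/MG/MD pseudo-atoms
to any admissible partner, and the achieving pair.  The grid agrees with
the independent single-pose `min_contact_map()`/`side_chain_energy()`
paths to 10⁻⁹ (tested).  `find_optimum()` takes the grid argmin (ties
broken toward smaller χ1, then χ2) and refines it by a deterministic
pattern search halving the step from 0.5° to 0.05°.

Pseudo-atoms replace side-chain methyl/methylene groups by their
mass-weighted centres (C = 12, H = 1) with a 2.00 Å radius; atomic radii
are H 1.20, C 1.60, N 1.50, O 1.45 Å.  Glycine's CA is formally a
methylene but is backbone and is kept atomic.  Groups are recognized
from the residue template, so missing hydrogens degrade gracefully to
the heavy-atom position.  Backbone hydrogens participate in the contact
search; side-chain protons appear only inside pseudo-atoms.

## 5. The synthetic generator

`generate_dataset()` emulates an archive of crystal structures at the
level the pipeline observes: helical polyalanine hosts with interior
isoleucines (every second position, so neighbours are always alanine),
true rotamers drawn per section from independent Gaussians, and observed
torsions distorted by the refinement-bias model

`observed = true + λ(res)·wrap(target − true) + N(0, σ_noise)`

where the target is the section mean plus a per-program offset and
λ(res) is 0 up to 1.2 Å, linear to λ_max at 3.5 Å.  λ_max defaults to
0.639 so that a target 20° from the truth pulls 10° at 3.0 Å — the
qualitative magnitude reported for low-resolution refinement bias.
Default study conditions, chosen once: section weights (0.4%, 0.4%, 6%,
10%, 12%, 52%, 3%, 10%, 6.2%) with more than half of the mass in
section 6 as in the archive; per-axis spread σ = 8°; section-6 mean at
(293°, 162°); resolutions uniform on [1.0, 3.0] Å; B factors log-normal
around 20 Å², clamped below 50 Å² so clean residues never trip the
filter.  Planted violations (inflated backbone B factors, or a deleted
CD1) are recorded in the ground-truth table so the filter audit can be
checked for exact precision/recall.

What the generator does **not** emulate: electron density and real
refinement (the bias model is a caricature with a single pull per
angle), correlated deposition (families of near-identical structures),
alternate conformations, non-helical hosts in the default spec, and
experimental noise structure beyond independent Gaussians.  Passing
tests therefore demonstrate that the pipeline measures what it claims on
data whose generative process is known — not that archive data satisfy
the generative model.

PDB output carries three-decimal coordinates; this rounding is the
dominant noise floor of the round trip and limits posed-vs-measured
torsion agreement to ≈ 0.1° (the tests use 0.2°).

## 6. Problem sizes and determinism

The test suite runs two full 1° scans (about half a minute each on one
CPU), a 2000-isoleucine recovery pipeline, an 8000-isoleucine
bias-signature experiment concentrated in two resolution bins, and a
10⁴-point Gaussian-fit oracle — sizes chosen so the statistical checks
have the power they need.  All randomness flows through explicit seeds;
the scans and the generator are bit-for-bit reproducible.

Statistical acceptance checks are phrased to have calibrated error
rates: binned means must lie within 3×SEM everywhere and within 2×SEM in
at least 90% of bins (a per-bin 2×SEM requirement across ~20 bins would
fail a correct pipeline more often than not), and section fractions must
fall inside 99% binomial envelopes widened by a 2-percentage-point
allowance for Gaussian leakage across section boundaries at σ = 8°.

## 7. Known limitations

* The steric field is a stand-in: its absolute energies are model units,
  and only well locations and relative depths are meaningful.
* The builtin secondary-structure assigner implements H/E/L only (no
  3₁₀/π distinction, no bulge handling beyond simple ladders); it is
  validated against ideal motifs, not against DSSP on real structures.
* The hairpin host is a calibrated idealization; real β-hairpins twist.
* Filters approximate an external quality-report step with local
  geometric sanity checks.
* mmCIF input is out of scope; PDB fixed-column format only.
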