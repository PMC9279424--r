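---
title: "Methods: quantifying class II fusogen conformational change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying class II fusogen conformational change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemotion)
```

# Scope

Class II membrane fusogens — the gamete fusogen HAP2 and its viral
relatives — convert from an extended prefusion monomer (domain order
D2–D1–D3) to a folded-back postfusion trimer. This vignette documents the
models, parameter choices and numerical conventions behind the four
quantitative readouts the package implements: rigid-body domain
kinematics, negative-stain projection matching, SEC-MALS protein-conjugate
mass analysis, and thermal-unfolding Tm extraction.

# Structures, numbering and correspondences

All residue addressing uses author (deposited) numbering; the package
never renumbers. Domain definitions are inclusive residue intervals per
chain, loadable from YAML. The shipped `hap2Domains()` set carries the
intervals that are fixed by construct boundaries (ectodomain 28–564, D1D2
fragment 28–457, hence D3 from 458), the three fusion loops (FL1 190–198,
FL2 209–214, FL3 143–149), the J0 strand (447–456) and the interim-sheet
segment (84–105). The exact D1/D2 boundary is not determined by any
construct, so `D1` ships as a placeholder equal to the D1D2 fragment and
is expected to be overridden by the user for per-domain analyses.

Structure parsing and writing delegate to `bio3d`. Alternate locations are
resolved to the highest-occupancy conformer; waters and hydrogens are
dropped by default; glycans and other heteroatoms are kept, but every
Cα-based selection excludes them by construction. Residue correspondences
come in three modes: `identity` (shared chain/residue keys, the default
when two states share numbering), `alignment` (Needleman–Wunsch on the
one-letter Cα sequences via `Biostrings`, match +1, mismatch −1, linear
gap −2, configurable) and `table` (user-supplied pairs, the route for
correspondences produced by structure-based aligners, which this package
deliberately does not reimplement).

# Rigid-body domain kinematics

`domainMotion()` follows a two-step protocol. First the post-state
structure is superposed onto the pre-state over the reference domain's
paired Cα atoms (proper-rotation least squares; reflections are forbidden
by the determinant correction in the Kabsch solution). Second, in that
reference-aligned frame, the least-squares rigid transform carrying the
pre-state mobile-domain Cα set onto the post-state set is computed and
decomposed:

* displacement: distance between the two Cα centroids (unweighted; Cα
  matches the superposition set, and an all-atom mass-weighted mode would
  mix in glycan placement, which is the less reproducible part of these
  models);
* rotation angle: `arccos((tr R − 1)/2)`, reported in [0°, 180°];
* rotation axis: from the skew-symmetric part of `R` for generic angles;
  within ~0.1° of 0° or 180° the +1 eigenvector is used instead, because
  the skew part degenerates there. Since the angle is unsigned, the axis
  is only defined up to sign; the reported sign makes the
  largest-magnitude component positive.

Degenerate inputs — fewer than three pairs, or (near-)collinear Cα sets,
detected by a second-singular-value threshold of 1e−8 relative — raise
errors rather than returning ill-conditioned fits. Orthogonality and
determinant of every `RigidTransform` are validated at 1e−6.

Two invariances characterize the decomposition and are enforced by tests:
applying one global rigid transform to both states changes neither angle
nor displacement, and swapping the roles of pre and post leaves both
unchanged (the rotation inverts; its angle does not).

`maxExtent()` is the maximal pairwise Cα distance (all-atom mode
available). The Cα convention is the natural match for rod-length
measurements on class averages, where glycans do not contribute visible
density at 25 Å.

# Density synthesis and projection matching

`synthesizeDensity()` places an isotropic Gaussian on every non-hydrogen
atom with integrated weight equal to the atomic number and
σ = resolution/(π√2) — the width at which the Gaussian's Fourier falloff
reaches the resolution cutoff — then applies an explicit Fourier low-pass:
unity below 0.75/resolution, cosine rolloff, zero at and beyond
1/resolution. At 25 Å (the negative-stain regime) this Gaussian-atom
approximation is indistinguishable from scattering-factor sums. The grid
is cubic, with padding ≥ 2σ so no atom sits near an edge, and the voxel
size must satisfy `voxelSize ≤ resolution/3` (default: equality), the
sampling needed for the filter edge.

`projectDensity()` rotates the density (ZYZ convention: the orientation
(θ, φ, ψ) is polar/azimuth of the viewing direction plus in-plane
rotation) by trilinear resampling and sums along the laboratory z axis.
Trilinear interpolation is a partition of unity, so total intensity is
conserved to interpolation accuracy (tested at 0.5%); its kernel slightly
smooths obliquely rotated copies, which is why "identical projections of
a spherical blob" holds at the few-percent level rather than exactly.

The template bank samples viewing directions on a ring-based hemisphere
grid (Friedel symmetry makes the opposite hemisphere redundant): rings at
multiples of the angular step, `ceiling(360·sinθ/step)` azimuths per ring
(half-span on the equator ring, which is self-redundant). Nearest-neighbor
spacing never exceeds the step. In-plane rotation is searched at match
time at the same step, and translation over integer pixel shifts
(default ±4; class averages are pre-centered, so the search range is
small). The score is the Pearson correlation over a circular mask
(default radius 90% of the image half-width; the published protocol's mask
shape is not specified, so circular is used) after zero-mean/unit-variance
normalization of the image under the mask — invariant to affine intensity
rescaling by construction. A zero-variance image under the mask is an
error, not a zero.

A practical note on identifiability: a rod-like particle is nearly
symmetric about its own axis, so the azimuth of the viewing direction is
not recoverable from projections — only the inclination is. Orientation-
recovery tests therefore use an L-shaped synthetic particle (rod plus
perpendicular arm), for which the full viewing direction is identifiable.

`particleLength()` binarizes at a threshold fraction of the image maximum
(default 0.2), keeps the largest connected component (EBImage labelling),
and returns the maximal pairwise distance between pixel centers times the
pixel size, computed on the component's convex hull. The pixel-center
convention means an n-pixel-long rod measures (n−1) pixel lengths.

# SEC-MALS protein-conjugate analysis

The conjugate model resolves an absorbing component (the glycoprotein)
and a non-absorbing modifier (detergent micelle or glycan) from three
detectors per elution slice:

* `UV = k_UV · ε_conj · c_conj` — the modifier does not absorb at 280 nm
  (glycan and detergent ε default to 0, overridable);
* `RI = k_RI · (dndc_conj·c_conj + dndc_mod·c_mod)`;
* `LS = k_LS · M_total · (dn/dc)_w² · c_total`, the zero-angle
  (form-factor 1) light-scattering relation — appropriate because these
  particles (~15 nm) are far below λ/20, and the analysis reports single
  masses, not radii.

The glycoprotein's own constants come from weight-fraction mixing of
protein and glycan values. Component masses are partitioned by solved
concentration (mass) fractions, `M_conj = M_total · c_conj/c_total` — the
partitioning convention is stated explicitly because commercial software
does not document its internal one. Peak summaries are
concentration-weighted (weight-average) masses over a user-chosen elution
interval.

Numerical conventions: calibration constants default to 1 (dimensionless
test mode; instrument constants enter via config). Solved concentrations
in (−clampTol, 0) are clamped to zero; anything more negative raises an
inconsistent-signals error. The default clampTol of 1e−6 g/L is a
numerical-dust tolerance appropriate for noise-free data; with real or
simulated detector noise the propagated concentration noise at the peak
tails easily exceeds it, so noisy analyses should set `clampTol` (and the
analogous `lsTol`) to a few times the propagated noise and average over a
peak interval that excludes the baseline. One estimator property worth
knowing: weight-averaging with noisy concentration weights is biased
upward at second order (E[c²] = c̄² + σ²), of order (σ/c)² relative —
well under 1% at 1% detector noise — so "unbiased" holds only to that
order.

# Thermal unfolding

The readout is the tryptophan fluorescence intensity ratio
FIR = F350/F330 on a linear thermal ramp; unfolding exposes tryptophans
and red-shifts emission, so FIR rises (a `sign` flag handles the opposite
polarity). The derivative is a Savitzky–Golay (local quadratic) smoothed
first derivative — exact on linear and quadratic curves — with a default
2.5 °C window (five points at the 0.5 °C ramp spacing used throughout;
the smoothing scale is not dictated by the instrument, so it is a config
parameter). A uniform temperature grid is required, as produced by a
linear ramp.

Tm is the temperature of the global positive derivative peak, refined to
sub-grid precision by a parabola through the peak and its two neighbors.
Qualifying transitions must be strict interior local maxima whose
topographic prominence reaches `minProminence` (default 0.25) of the
global peak height — measured against the global peak so that noise
ripple is not promoted to extra transitions — and must exceed a
machine-epsilon-scaled floor so that flat or purely linear curves raise a
no-transition error instead of returning roundoff ripple. The onset is
the lowest temperature at which the smoothed derivative first reaches 10%
of the peak height on the way up to Tm; 10% is a package default, since
the onset criterion is conventionally left unstated. Duplicate capillaries
are summarized as mean ± half-range (difference from the mean), matching
the reporting convention for duplicate melts, not a standard deviation.

# Synthetic generators: what they emulate, and what they do not

Every analysis stage has a generator that is a pure function of a single
integer seed (the global RNG state is saved and restored, so generators
never perturb a session's randomness):

* `genRodStructure()`: a collinear chain of helical Cα domains. Defaults —
  four domains of 38.75 Å, i.e. a 155 Å rod of 120–160 residues — mirror
  the extended four-density monomer geometry seen for HAP2. It emulates
  rod topology and domain boundaries, not side chains, secondary-structure
  diversity or glycans.
* `applyMotion()`: rotates one domain about its centroid by a known
  axis-angle and displaces the centroid by a known distance (direction is
  a free parameter, unit x by default), optionally adding Gaussian Cα
  noise to the moved domain — the ground-truth factory for the kinematics.
  0.5 Å noise represents coordinate uncertainty between independently
  refined structures.
* `genClassAverage()`: a projection plus white Gaussian noise at a stated
  SNR (signal SD over the particle support / noise SD). It does not model
  stain granularity, CTF, or alignment/averaging artifacts of real class
  averages — so passing recovery tests demonstrates estimator correctness
  under the stated noise model, not robustness to negative-stain texture.
* `genChromatogram()`: a Gaussian elution peak of a stoichiometric
  glycoprotein–micelle complex (defaults: 186,300 Da trimeric glycoprotein,
  i.e. 3 × 62,100 Da monomer, plus a 75,770 Da micelle) pushed through the
  forward detector model with 1% channel noise. No band broadening,
  inter-detector delay or baseline drift.
* `genMeltCurve()`: a two-state sigmoid (width 1.5 °C) between linear
  baselines on the 20–95 °C ramp at 0.5 °C steps, 1% amplitude noise.
  No aggregation tails or scattering artifacts.

# Problem sizes and test design

The suite runs the estimators at sizes chosen to make the statistics
meaningful while keeping the whole suite at around two minutes: 40-residue
domains for kinematics recovery (100 noisy seeds), a 10,000-rotation
brute-force oracle for superposition optimality, 1,000 seeded chromatogram
replicates, 200 melt replicates, and 100 seeded orientations against a
30° template bank (24 templates) for projection matching. The headline
structural magnitudes (168°/76 Å motion, 155 Å extent, 3.4 Å model RMSD)
are exercised on synthetic stand-ins constructed at those magnitudes,
since the deposited structures cannot be bundled; the same entry points
accept user-supplied PDB/mmCIF files directly.

# Known limitations

* The fallback sequence aligner is a plain global alignment; for
  cross-species comparisons at low sequence identity a structure-based
  correspondence should be supplied as a user table.
* Projection matching searches integer-pixel shifts only and assumes
  pre-centered class averages; there is no sub-pixel refinement.
* The MALS model has no band-broadening correction and no angular
  (Zimm/Berry) extrapolation; it is a zero-angle treatment.
* Tm extraction is model-free (derivative peak); it does not fit
  thermodynamic parameters (ΔH, ΔG) and reports no van't Hoff quantities.
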