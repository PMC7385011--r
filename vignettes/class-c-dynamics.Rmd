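---
title: "Structural dynamics of multi-domain GH9 endoglucanases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural dynamics of multi-domain GH9 endoglucanases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clefscope)
```

## The scientific setting

Plant class C endoglucanases digest crystalline cellulose with a
three-part architecture: a catalytic glycoside hydrolase family 9 (GH9)
domain of roughly 450 residues, a linker of under 100 residues, and a
CBM49 carbohydrate-binding module of roughly 40–200 residues. The
questions this package operationalises are geometric and dynamic: which
positions of a structure family form a rigid invariant core; how mobile
are the linker and CBM49 relative to the catalytic domain; which residue
segments move in concert across domain boundaries, and how much surface
do those interfaces bury; how do family members cluster in coordinate
space; and what are the dimensions and residue composition of the
substrate-binding groove.

All analyses run at C-alpha resolution. That is a deliberate modelling
choice: homology models of this family are reliable at backbone level
and every quantity of interest here (elastic-network modes, fluctuation
profiles, cross-correlation, core volumes, coordinate PCA, groove
geometry at probe scale) is well defined on C-alpha traces. Side chains
enter only through effective sphere radii.

## Elastic-network model

`build_hessian()` implements the anisotropic network model (ANM): every
pair of C-alpha atoms closer than a cutoff is joined by a Hookean
spring of stiffness gamma, giving off-diagonal 3x3 superblocks
$H_{ij} = -\gamma\, \mathbf{d}\mathbf{d}^T / |\mathbf{d}|^2$ with
$\mathbf{d} = \mathbf{x}_j - \mathbf{x}_i$, and diagonal superblocks
that enforce row sums of zero (translation invariance). Defaults are
**cutoff = 15 Å** and **gamma = 1** (dimensionless): the standard
C-alpha ANM regime in which the low-frequency spectrum is insensitive
to the cutoff and the spring constant only scales the spectrum. Because
the energy scale is arbitrary, frequencies are reported as
$\omega_k = \sqrt{\lambda_k}$ in arbitrary units; absolute frequencies
published for particular minimised all-atom models are model-dependent
and are not comparable across force fields, so the package makes no
attempt to match any specific numeric scale. Mass weighting is omitted:
at C-alpha resolution all beads carry the same effective mass, so
weighting would only rescale the spectrum.

A connected, non-collinear structure has exactly six zero modes (rigid
translations and rotations). `normal_modes()` classifies an eigenvalue
as zero when $\lambda < 10^{-8}\lambda_{\max}$ and raises a
disconnected-structure error when more than six qualify. Mode indexing
is 1-based; the k-th non-trivial mode is mode $6+k$, and the default
analysis window is **modes 7–18**, the customary low-frequency band for
locating domain-scale flexibility.

Mode-derived fluctuations are
$\mathrm{rmsf}_i = \sqrt{\sum_k \lambda_k^{-1} |\mathbf{v}_{k,i}|^2}$
over the selected modes (relative units), and ensemble-derived
fluctuations are the root mean squared deviation of each residue about
its frame mean (Å), computed on pre-superposed frames. Each profile
carries two summary scores used for comparing full-length against
truncated enzyme forms: `delta`, the max-minus-min of the profile, and
`sigma`, its standard deviation.

The dynamic cross-correlation map is
$C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
\sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}$. Both
sources are provided and cross-validated against each other in the test
suite: the mode route inverts only the selected modes
($\langle \Delta r_i \cdot \Delta r_j\rangle =
\sum_k \lambda_k^{-1}\mathbf{v}_{k,i}\cdot\mathbf{v}_{k,j}$), and the
ensemble route uses the frame mean as reference. Which of the two a
published map used is often unknowable; the package asserts neither and
exposes both.

## Superposition and the invariant core

Rigid superposition is the SVD form of the Kabsch solution with
reflection correction, so the rotation is always proper. The reference
structure for ensemble fits is the first in input order (configurable).

The invariant core of a family is found iteratively
(`find_invariant_core()`): superpose all structures on the current
candidate column set, summarise each aligned column's positional
scatter as the volume of the ellipsoid whose semi-axes are the square
roots of the eigenvalues of the 3x3 positional covariance,
$V = \tfrac{4}{3}\pi\sqrt{\lambda_1\lambda_2\lambda_3}$, and remove the
single worst column until every surviving volume is below the cutoff
(**1.0 Å³** by default) or a floor size is reached. Numerical choices,
fixed once and documented here:

* the covariance uses the population denominator (1/n) — volumes are
  compared with one another, so only consistency matters;
* negative eigenvalues from roundoff are clamped to zero, making
  coplanar scatter report exactly zero volume;
* ties on the worst volume remove the lowest column index, which makes
  the removal order deterministic;
* one column is removed per iteration (no batching), and the family is
  re-superposed after every elimination — re-superposition lets the fit
  progressively concentrate on the emerging core, and a config switch
  (`resuperpose = FALSE`) gives the cheaper fit-once variant;
* the cutoff is applied per column; a total-volume criterion is
  available as `criterion = "total"` for users who read "least volume"
  as a sum.

## Interaction surfaces

Correlated segment detection scans a DCCM for maximal rectangular
blocks of entries at or above `r_min` between residue runs that are at
least `min_len` long, confined to one annotated domain, and separated
by at least `min_separation` in sequence. Defaults **r_min = 0.8,
min_len = 4, min_separation = 10**: correlations described as
"essentially 1" in the literature survive any threshold in this range,
runs shorter than 4 residues are noise-prone, and the separation floor
removes the trivially correlated diagonal band. All three are exposed
as arguments and echoed in output headers. Detected segments receive
sublabels (G1..Gk, C1..Ck, L) by ascending start position, and segment
pairs are classified by the domain set of their connected component:
two-domain components are GC, GL or CL surfaces, and a component
touching all three domains is the three-way class GLC.

Buried interface area uses a Shrake–Rupley quadrature over a
deterministic golden-section spiral of **960 points** per sphere with a
**1.4 Å** probe. At C-alpha resolution each residue is one sphere of
radius **3.0 Å**, an effective radius approximating side-chain extent;
absolute areas from this model are therefore on a residue-sphere scale
and are labelled as such — they are not expected to match all-atom
surface programs numerically, only in ordering and magnitude class.
BSA(A, B) = SASA(A) + SASA(B) − SASA(A∪B), computed with the rest of
the structure absent so the value isolates the A–B interface.

## Groove geometry and the cylinder approximation

The cylinder approximation reduces a measured groove area/volume pair
$(A_o, V_o)$ to $r = \sqrt{A_o/4\pi}$, $h = 4V_o/A_o$, $l = A_o/r$,
with closed-cylinder area $A_c = 2\pi r(r+h)$, volume
$V_c = \pi r^2 h$, and approximation constants $\phi = |A_o - A_c|$,
$\beta = |V_o - V_c|$. Two identities follow by substitution and are
enforced as tests rather than assumptions: $V_c \equiv V_o$ (so
$\beta \equiv 0$ up to print rounding — which is why published tables
of this model show a uniform 0.00 volume differential) and
$l \equiv 4\pi r$. `cylinder_from_groove()` accepts measured pairs
directly, so verifying published fits never depends on the package's
own pocket detection.

`grid_groove_measure()` is the package's own cavity detector, a grid
flood-fill: cells inside any probe-inflated residue sphere are
obstacles; empty cells reachable from the bounding-box boundary
(6-connectivity) are bulk solvent; the unreachable remainder are
pocket/groove candidates, reported per connected component with
$V_o$ = cell count × spacing³ and $A_o$ = exposed voxel faces ×
spacing². The voxel-face estimator systematically overestimates smooth
areas (by up to ~1.5x for oblique surfaces); halve the spacing to check
convergence — the grid origin is snapped to a fixed coarse unit so
refined grids nest. Default spacing **0.5 Å** within the supported
range [0.25, 2.0]. Lining residues are those whose inflated sphere
surface passes within probe + spacing of the component, and
`assign_groove_domains()` labels each groove by the set of domains
contributing lining residues (GH9, L, CBM49, or concatenations such as
LC and GLC in fixed G–L–C order).

## Coordinate PCA and quadrant clustering

`coordinate_pca()` eigen-decomposes the mean-centred, unscaled
covariance of flattened member coordinates over aligned columns
(optionally restricted to the invariant core); the retained component
count is min(S−1, 3C). Covariance rather than correlation is used
because coordinates share units and their variances are the signal.
Each component's sign is fixed by making its largest-magnitude loading
positive, so projections are reproducible up to that documented
reflection. `quadrant_cluster()` labels members by the projection signs
on a chosen component pair, zeros assigned to the positive side. The
default axis pair is (1, 3), following the observation in this enzyme
family that the first and third components resolve the groups best;
the synthetic-data validation uses (1, 2) because there the two planted
between-cluster directions are, by construction, the two leading
components.

## Residue set algebra

Active-site composition works on parsed one-letter residue lists. The
combined set is AA = AA^Dock ∩ AA^CvG, and the expected containment in
the interaction-surface set AA^IS is *reported* (flag attribute), never
silently filtered. Composition classes are frozen as AAA = {W,F,Y},
P, RKNQ = {R,K,N,Q}, ST = {S,T}, HSC = {L,I,V,A,M} and the
catalytic-propensity class CAT = {D,E,C,H}; the classes are disjoint
(S and T count only in ST), glycine is untracked, and CAT exists to
verify that binding grooves exclude catalytically competent residues.
Published plain-text residue lists cannot recover the typographic
distinction some tables use to mark the cavity-lining subset, so such
lists are ingested as the union, and the Discussion-style class
percentage ranges that depend on that subset are not asserted anywhere.

## The synthetic data generators

Every stage of the pipeline is validated on seeded synthetic data
(`synthetic_spec()`, `make_multidomain_structure()`, `make_ensemble()`,
`make_family()`, `sample_mode_ensemble()`), built to emulate the
statistical structure the analyses assume:

* **Architecture.** GH9 and CBM49 are compact self-avoiding bead clouds
  (minimum inter-bead distance 3.5 Å, random sequential packing at a
  fraction safely below the jamming limit) joined by a semi-extended
  helical linker (axial rise 2 Å/residue, radius 3 Å). Default counts
  450/60/110 mirror the family's domain sizes. The helical linker is a
  numerical necessity as much as a realism choice: a straight bead
  chain is a first-order mechanism of the anisotropic network (free
  transverse bending) and would contaminate the six-zero-mode
  structure, whereas a helix resists bending at first order.
* **Ensembles.** Frames add per-domain isotropic Gaussian displacements
  — defaults sigma(GH9) = 0.3 Å, sigma(L) = sigma(CBM49) = 1.5 Å per
  axis, a 5:1 mobility ratio encoding the linker/CBM hypermobility the
  family exhibits — plus a random rigid rotation and translation per
  frame so superposition is genuinely exercised. 500 frames by default.
* **Families.** Members share the base sequence (gap-free alignment),
  with 0.05 Å noise on the GH9 core, 3 Å noise on the periphery, and a
  per-cluster rigid displacement of the whole CBM49 block. The two
  cluster-shift directions are orthogonal with *distinct* magnitudes
  (8 and 5 Å): equal magnitudes would make the two between-cluster
  eigenvalues degenerate and the leading principal plane arbitrary up
  to rotation, turning quadrant membership into a coin flip. Distinct
  magnitudes pin the component order; quadrant labels remain arbitrary
  only up to the documented sign convention, which label matching in
  the tests absorbs.
* **Seeding.** One global seed drives a named substream per generator
  (hash of the operation name mixed into the seed), so adding a
  generator never perturbs the draws of another, and identical specs
  reproduce outputs bit-exactly.

What the generators deliberately do **not** emulate: folded secondary
structure, sequence-realistic composition, anharmonic dynamics, or
solvent. Consequently, passing the planted-recovery tests demonstrates
that the algorithms recover the structure they are designed to detect
under the stated noise model — it does not certify performance on real
conformational ensembles, whose correlations are richer than the
isotropic Gaussian + rigid-shift model used here.

## Validation sizes and conventions

The test suite and the acceptance script run the generators at the
default study conditions where the claim depends on them (620-residue
architecture for mobility ratios; 40-member families for core recovery
and cluster recovery) and at reduced sizes (90–130 aligned columns)
where only algorithmic correctness is at stake; the mode-vs-ensemble
DCCM cross-check samples 10^5 frames on a 20-residue model. All
indices — residues, alignment columns, modes — are 1-based throughout,
matching R convention and the author-numbering style of published
residue tables (e.g. W554). Author PDB numbering is preserved verbatim;
insertion codes are rejected rather than silently merged, since
homology models do not carry them.

## Known limitations

* C-alpha sphere SASA is an effective-scale model; compare trends, not
  absolute areas, against all-atom programs.
* The voxel surface estimator biases groove areas upward; volumes are
  the reliable grid quantity.
* Block detection in `correlated_segments()` enumerates row intervals
  and is quadratic in the longest domain run; it is intended for maps
  up to a few hundred residues per domain, which covers this enzyme
  family.
* One printed family groove row is internally inconsistent with the
  cylinder identity by 0.003 Å beyond print-rounding slack (its radius
  back-computes to a value that rounds differently); the package
  reports the discrepancy as measured rather than special-casing the
  row.
* `run_pipeline()` is deterministic end-to-end for a fixed config and
  seed; floating-point reproducibility assumes the single-threaded
  reference BLAS behaviour of a standard R build.
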