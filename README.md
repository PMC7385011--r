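# clefscope

Structural-dynamics analysis of multi-domain carbohydrate-active
enzymes, built around plant **class C GH9 endoglucanases** — enzymes
that digest crystalline cellulose with a catalytic glycoside hydrolase
family 9 (GH9) domain, a flexible linker, and a CBM49
carbohydrate-binding module. The package is for structural
bioinformaticians who want to ask, of a family of C-alpha models: which
positions form the rigid invariant core, how mobile are linker and CBM
relative to the catalytic domain, which segments move in concert across
domain boundaries and how much surface do those interfaces bury, how do
family members cluster in coordinate space, and what are the dimensions
and residue composition of the substrate-binding groove.

## What it computes

* **Structures and alignments** — C-alpha PDB reading/writing with
  altloc resolution, FASTA/Clustal alignment maps, domain annotation
  (GH9 / L / CBM49), and matched-residue "corrected subsets" for
  full-length vs truncated comparisons.
* **Superposition and invariant core** — Kabsch superposition, ensemble
  alignment on ungapped columns, and iterative core detection: each
  aligned column's scatter is the volume of the ellipsoid
  V = (4/3)·π·√(λ₁λ₂λ₃) of its positional covariance; the worst column
  is removed (re-superposing each round) until all survivors fall below
  a cutoff (default 1.0 Å³).
* **Elastic-network dynamics** — anisotropic network model Hessian
  (cutoff 15 Å), normal modes with zero-mode accounting, mode- and
  ensemble-derived RMSF with Δ (max−min) and σ summary scores, and
  dynamic cross-correlation maps from either modes or frames.
* **Interaction surfaces** — maximal blocks of high positive
  correlation between sequence-distant, domain-pure residue runs;
  classification into GC / GL / CL and the three-way GLC surfaces;
  buried area via Shrake–Rupley quadrature on a residue-sphere model.
* **Coordinate PCA and quadrant clustering** of structure families.
* **Groove geometry** — grid flood-fill cavity/groove measurement, and
  the cylinder approximation of a groove: from observed area and volume
  (A_o, V_o),

      r = √(A_o / 4π),   h = 4 V_o / A_o,   l = A_o / r,
      A_c = 2πr(r + h),   V_c = πr²h,
      φ = |A_o − A_c|,    β = |V_o − V_c|,

  with the analytic identities V_c ≡ V_o and l ≡ 4πr.
* **Active-site set algebra** — parsing published residue lists,
  AA = AA^Dock ∩ AA^CvG with containment reporting against AA^IS, and
  amino-acid class composition (aromatics {W,F,Y}, P, {R,K,N,Q},
  {S,T}, short hydrophobics {L,I,V,A,M}, catalytic {D,E,C,H}).
* **Synthetic data** — seeded generators for multi-domain structures,
  mobility-stratified ensembles and clustered families, so the whole
  pipeline is testable end to end without external data.

Bundled reference tables (`inst/extdata/`) carry the published groove
measurements of the four laboratory-characterized class C enzymes
(UniProt Q5NAT0, Q8LJP6, Q93WY9, Q9ZSP9), the groove cylinder fits of
39 putative family members, and the four published contact-residue
lists.

## Worked example

Cylinder model of the *O. sativa* enzyme's measured binding groove
(A_o = 905 Å², V_o = 616 Å³):

```r
library(clefscope)
cylinder_from_groove(905, 616)
#> <cylinder_approx> A_o 905.00 A^2, V_o 616.00 A^3
#>   r 8.49  h 2.72  l 106.64  A_c 597.67  V_c 616.00  phi 307.33  beta 0.00
```

The groove is approximated by a shallow cylinder of radius 8.5 Å and
height 2.7 Å whose unrolled length (~107 Å) spans most of the enzyme —
consistent with a surface channel that guides a cellulose chain rather
than a closed pocket. The volume differential β is identically zero (a
property of the model, not a fit result), while φ ≈ 307 Å² measures how
far the real groove's corrugated surface departs from a smooth cylinder.

Composition of the published *O. sativa* contact-residue list:

```r
composition(active_site_table()$Q5NAT0)
#> <composition_stats> n = 28
#>   AAA    6/28 =  21.4%
#>   P      2/28 =   7.1%
#>   RKNQ   5/28 =  17.9%
#>   ST     3/28 =  10.7%
#>   HSC   10/28 =  35.7%
#>   CAT    1/28 =   3.6%
```

Aromatics and short hydrophobics dominate (57% together) while
catalytic-propensity residues are nearly absent (one aspartate) — the
signature of a chemically inert binding groove feeding a separate
catalytic site.

Invariant-core recovery on a synthetic 40-member family with a planted
rigid GH9 core and mobile linker/CBM periphery:

```r
sp  <- synthetic_spec(n_gh9 = 90, n_linker = 12, n_cbm = 30,
                      n_members = 40, seed = 0)
md  <- make_multidomain_structure(sp)
fam <- make_family(md$structure, md$annotation, sp)
find_invariant_core(fam$structures, fam$map, cutoff = 1.0, min_core = 10)
#> <core_result> 90/132 columns in core (cutoff 1 A^3), 42 removed
```

All 90 planted core columns survive; all 42 mobile columns are
eliminated.

A full run over every stage (`run_pipeline(pipeline_config())`) writes
per-stage TSVs (core, modes, rmsf, dccm, surfaces, pca, grooves,
activesite) plus a `summary.yaml` of parameters, seed and timings.

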