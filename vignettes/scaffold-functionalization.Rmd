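---
title: "Substituent placement on frozen scaffolds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substituent placement on frozen scaffolds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ScaffoldSpace)
```

## The problem

High-throughput exploration of homogeneous catalysts and related
transition-metal chemistry needs large families of 3D structures that
differ only in the substituents decorating a common scaffold. Full
quantum-chemical geometry optimization of every member is the cost
bottleneck; generating each member from a 2D sketch throws away the
carefully optimized core geometry one usually already has. ScaffoldSpace
takes the third route: keep the core of an input geometry exactly as
supplied (typically DFT-optimized) and add substituents by geometric
construction, relieving only the local steric strain of the newly placed
group. The output is a structure whose skeleton is bit-identical to the
input and whose substituents are reasonable starting points for any
higher-level refinement the user chooses to run afterwards.

## The placement model

A functionalization site is an ordered index pair `[b, a]`: `b` is a
terminal atom to be replaced (almost always a hydrogen) and `a` is the
scaffold atom that receives the new bond. A substituent library entry
consists of a geometry, the index of its *central atom* (the atom that
will bond to `a`), and the *centroid point* of the central atom's bonded
neighbours — for CH3, the centroid of the three hydrogens; for NH2, the
midpoint of the two hydrogens. We generalize this to the arithmetic mean
over all bonded neighbours, so any coordination works.

Placement is four deterministic steps:

1. **Orientation.** The unit vector from the centroid point to the
   central atom is the substituent's free-valence direction. A minimal
   rotation (Rodrigues construction) maps it onto the negated `a -> b`
   direction, so the free valence points at the anchor. We fix the sign
   convention once — central atom minus centroid — because the tetrahedral
   and planar textbook definitions of the centroid vector point in
   opposite senses relative to the free valence; with this convention the
   existing bonds always end up facing away from the scaffold. When the
   two directions are antiparallel the rotation axis is degenerate; we
   rotate 180° about the Cartesian basis vector least aligned with the
   free valence, Gram–Schmidt-orthogonalized, which is deterministic and
   involves no randomness.
2. **Translation.** The central atom is placed on the `a -> b` ray at the
   new-bond distance. The default bond-length policy is the sum of the
   two covalent radii from the bundled table (Cordero 2008 values,
   low-spin radii for the ambiguous transition metals); a per-call
   numeric override is available.
3. **Merge.** Atom `b` is deleted — all higher indices shift down by one —
   and the substituent atoms are appended after the surviving skeleton
   atoms in their original order, with a single new `a`–central bond.
   Later pairs in a serial list must be written against this updated
   numbering; `autoFunctionalizationSpec()` does that bookkeeping
   mechanically and is the recommended way to build long lists.
4. **Constrained relaxation.** Only atoms with `skeletonMask == FALSE`
   may move (see below).

Torsion about the new bond is not determined by aligning one vector. The
default keeps the residual orientation of the minimal rotation and lets
relaxation fix clashes; an optional scan over 12 torsions at 30°
increments picks the rotamer maximizing the minimum substituent–skeleton
distance (ties broken toward the smallest angle) as a cheap robustness
option.

Indexing is 1-based everywhere a user touches an index — functionalization
pairs, the library CSV's `central_atom_index`, coordinate rows — matching
both R convention and the Molfile bond block.

## Serial runs and the frozen skeleton

`runSerial()` chains placements: step *k*'s output is step *k+1*'s input.
At the start of each step the entire current structure is re-frozen and
only the atoms placed in that step are movable. The original skeleton is
therefore transitively frozen across the whole run — not merely to
numerical tolerance but exactly, because frozen coordinates are copied,
never recomputed: relaxation zeroes the gradient on frozen atoms *and*
copies the input coordinates back onto them afterwards, so the invariant
holds regardless of backend numerics.

The price of never relaxing the core is a systematic error that grows
with each placement: every new group is built on the slightly-off
geometry left by the previous one. On realistic systems the deviation
from a higher-level reference grows nearly linearly with the step number.
`rmsdTrendFit()` fits that line and predicts the step at which a
user-chosen deviation threshold is reached — the natural point to insert
one full higher-level re-optimization (`fullStructureHook()`) and
continue with the refreshed structure as a new skeleton.

## Relaxation backends

The relaxation contract is "clash-free, skeleton frozen", not specific
force-field energies. Two external backends (GAFF, then UFF — in that
order, the second catching parameterization gaps of the first) are
invoked out-of-process through Open Babel via Molfile exchange when
`obabel` is on the PATH. They are optional: the builtin backend is a
steepest-descent minimizer with Armijo backtracking on a deliberately
non-physical steric objective,

* bonds touching movable atoms: `k (r - r0)^2` with `k = 1` and `r0` the
  covalent-radius sum;
* nonbonded pairs with at least one movable atom: `(sigma / r)^12` with
  `sigma = 0.8 ×` the covalent-radius sum.

Units are arbitrary; the objective exists to push overlapping atoms apart
and keep bond lengths sane, nothing more. Defaults: gradient
infinity-norm tolerance `1e-3`, at most 500 accepted steps.
Non-convergence is a warning, not an error — the best structure found is
returned and flagged in the per-step log, which is the right behaviour
mid-batch. In the study-scale batch below roughly 1% of steps hit the
step cap; their structures are still clash-free by inspection of the
objective, just short of the tight gradient tolerance.

## Quality metrics

`kabschAlign()` (SVD with determinant correction) and
`quaternionAlign()` (Horn's closed form, dominant eigenvector of the 4×4
key matrix) solve the same optimal-superposition problem by independent
routes; they agree to `1e-8` on random point sets in the test suite, and
both exclude reflections. `hrmsd()` measures the root-mean-square
deviation over heavy atoms (everything except H) after optimal
superposition — the standard metric for comparing the same complex
optimized by different methods. Correspondence is by index by default,
which is the right choice for method-vs-method comparisons of one
structure; `reorder = TRUE` re-derives it per element with a Hungarian
assignment on the distance matrix after centroid pre-alignment (the
solver is written in-package and oracle-tested against brute-force
permutation search, as no installed package provides one).

`rmsdSummary()` reports mean, **population** standard deviation, max and
n. ΔΔE bookkeeping (`ddE()`, `ddESummary()`) is plain arithmetic on
user-supplied energies: the reaction energy from fully optimized
geometries minus the same reaction from single points on cheaper
geometries, canonically in kcal/mol with fixed hartree/eV conversion
constants on input.

## Descriptors and the gap model

`coulombMatrix()` implements the standard Coulomb matrix (diagonal
`0.5 Z^2.4`, off-diagonal `Z_i Z_j / d_ij`, distances in Å with no unit
conversion) with row-norm sorting and zero padding to a fixed capacity
(default 200 atoms). The stored vector is the upper triangle including
the diagonal of the sorted, padded matrix — a layout choice; any fixed
flattening works as long as train and predict agree, which
`predictGap()` enforces by length. `trainGapModel()` fits an extreme
gradient-boosted tree ensemble on a seeded 75–25 split and reports both
the coefficient of determination (headline) and the squared Pearson
correlation, because "R²" means either depending on the community.
Booster hyperparameters are library defaults, exposed through `params`.

## The synthetic fixtures

Everything is testable offline through deterministic toy systems:

* a planar 12-carbon macrocycle with four terminal hydrogens on
  alternating ring atoms (16 atoms) — a macrocycle-like stand-in for a
  porphyrin-type scaffold;
* a Pd centre with four planar NH2 donors at 2.0 Å (13 atoms, eight
  terminal H sites) — minimal donor groups rather than full ring ligands,
  kept tiny on purpose;
* benzene; and
* a substituent library {H, CH3, NH2, OH, F} with ideal geometries. The
  single-atom entries carry an explicit centroid point, since an isolated
  atom has no bonded neighbours to average; their orientation is
  irrelevant at placement time.

`batchFixture()` reproduces a study-scale crossed design: 10 skeleton
variants (the macrocycle rigidly rotated in-plane, then pre-decorated
with one CH3 so all variants share a single atom numbering and each spec
transfers across them) × 4 substituent sets × 28 serial sites, emitting
every intermediate — 1120 structures, which the acceptance script
enumerates in well under ten minutes on one CPU. These fixtures exercise
the engine's contracts (counts, frozen cores, bond-length policy,
determinism); they do not emulate conformational flexibility, ligand
hemilability, or the force-field-quality errors of real organometallic
systems, so passing tests certify the construction machinery, not
chemical accuracy on real complexes. Flagging suspiciously large
heavy-atom RMSDs — e.g. from a partially detached donor arm — remains the
user's job, with `compareDirectories()` + `rmsdTrendFit()` as the tools.

## Numerical choices and edge cases

* Bond perception adds a single bond where the distance is at most
  `tolerance × (r_i + r_j)` (default 1.15); it is idempotent and keeps
  existing bonds. Perceived orders are always 1 — downstream code treats
  orders as topology, never chemistry. H2 at 0.74 Å sits just above the
  default threshold (0.713 Å) and is only bonded at tolerance ≥ 1.20: for
  very short X–H bonds, prefer Molfile input or a raised tolerance.
* Molfile I/O is V2000 only; V3000 is rejected explicitly. Coordinates
  round-trip at the format's 4 decimals; charges use `M  CHG` records.
* Molecules reject atom pairs closer than 0.3 Å at construction, so
  pathological overlaps fail fast rather than exploding the repulsion.
* Superposition of degenerate (collinear) point sets still returns a
  proper rotation; the quaternion route's dominant eigenvector is well
  defined there and the SVD route's determinant correction handles the
  rank deficiency.
* All randomness (fixture noise, train/test splits, boosting) flows from
  explicit seeds; placements and relaxations are seed-free deterministic.

## Interfaces

The spec-facing surface is functions plus a thin command-line script,
`system.file("scripts", "scaffoldspace.R", package = "ScaffoldSpace")`,
with subcommands `functionalize`, `batch`, `rmsd`, `trend`,
`descriptors`, `train-gap`, `fixtures`; every run writes a JSON manifest
(inputs, settings, per-step log) sufficient to reproduce it. A flat YAML
config can supply any flag's default; explicit flags win.

## A worked example

```{r example}
lib <- fixtureSubstituentLibrary()
ring <- toyMacrocycle()
spec <- autoFunctionalizationSpec(ring, c("CH3", "NH2", "OH"), lib)
run <- runSerial(ring, spec, lib)
run$log
```

```{r frozen}
# the original ring atoms never moved
out <- run$structures[[3]]
max(abs(coords(out)[1:12, ] - coords(ring)[1:12, ]))
```

```{r hrmsd}
# heavy-atom RMSD between the first and last intermediate's shared core
hrmsd(run$structures[[1]], ring)
```

## Known limitations

* Only terminal atoms can be replaced; bridging (multi-attachment)
  substituents and non-terminal substitution are out of scope.
* The builtin objective has no attractive nonbonded term and no angular
  terms: it relieves clashes but does not produce force-field-quality
  rotamers. Use the external backends or a full-structure hook when
  rotamer quality matters.
* Bond orders from XYZ input are perceived as single bonds only.
* No conformer search: one placement yields one structure.
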