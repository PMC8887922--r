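# ScaffoldSpace

Automated placement of substituent groups on 3D molecular scaffolds —
including transition-metal complexes — with a frozen-skeleton guarantee,
plus the quality-control toolkit needed to trust the results at scale.

## Who this is for

Computational chemists exploring the *local chemical space* of a scaffold:
you have one carefully optimized core geometry (say, a DFT-optimized metal
complex) and want hundreds of decorated variants as credible 3D starting
structures without re-optimizing the core every time, e.g. for
high-throughput screening or for training structure–property models.

## What it does

**Placement.** A site is an ordered pair `[b, a]`: terminal atom `b`
(usually H) is replaced, scaffold atom `a` receives the new bond. Each
library substituent stores its central atom and the centroid of that
atom's bonded neighbours; the unit vector from centroid to central atom is
the free-valence direction. Placement rotates the substituent so this
direction points at `a` (minimal Rodrigues rotation; deterministic
180°-axis choice in the antiparallel case), puts the central atom on the
`a -> b` ray at the covalent-radius-sum distance `r_cov(a) + r_cov(c)`,
deletes `b`, and merges connectivity. Serial runs chain steps; only each
step's new atoms relax (builtin steric minimizer, or GAFF/UFF via Open
Babel when available) while every other atom stays **bit-identical** to
its input coordinates.

**Quality control.** Heavy-atom RMSD after optimal superposition by two
independent routes (Kabsch SVD and Horn quaternion),

    RMSD(p, q) = sqrt( (1/n) * sum_i || p_i - q_i ||^2 ),

minimized over rigid transforms; optional Hungarian atom reordering per
element; batch statistics (mean, population sd, max); a linear fit of
RMSD growth across a serial run that predicts when to insert a
higher-level re-optimization; and reaction-energy bookkeeping
`ddE = deltaE_opt - deltaE_sp` (kcal/mol) for assessing geometries along
the energy dimension.

**Descriptors & learning.** Standard Coulomb matrices (diagonal
`0.5 Z^2.4`, off-diagonal `Z_i Z_j / d_ij`, row-norm sorted, zero-padded,
default capacity 200 atoms) and a seeded gradient-boosted regression
harness (75–25 split) for HOMO–LUMO-gap prediction.

## Worked example

```r
library(ScaffoldSpace)

lib  <- fixtureSubstituentLibrary()            # H, CH3, NH2, OH, F
ring <- toyMacrocycle()                        # 16-atom planar scaffold
spec <- autoFunctionalizationSpec(ring, c("CH3", "NH2", "OH"), lib)
run  <- runSerial(ring, spec, lib)
run$log
#>   step substituent natoms backend converged objectiveBefore objectiveAfter
#> 1    1         CH3     19 builtin      TRUE     0.002135057   0.0009363738
#> 2    2         NH2     21 builtin      TRUE     0.001549679   0.0007450376
#> 3    3          OH     22 builtin      TRUE     0.000694336   0.0005926698

max(abs(coords(run$structures[[3]])[1:12, ] - coords(ring)[1:12, ]))
#> [1] 0
```

Three placements grow the ring from 16 to 22 atoms; the steric objective
drops at every step, and the original ring coordinates are untouched to
the last bit. `writeMolfile()` saves any intermediate; `executeBatch()`
crosses skeleton and spec lists, writing `<skeleton>_<spec>_func_<k>.mol`
per step.

A command-line front end with subcommands `functionalize | batch | rmsd |
trend | descriptors | train-gap | fixtures` ships at
`system.file("scripts", "scaffoldspace.R", package = "ScaffoldSpace")`;
each run writes a JSON manifest that fully reproduces it.

## Package layout

- `R/` — S4 classes (`Molecule`, `Substituent`, `SubstituentLibrary`,
  `AlignmentResult`) with validity checks and accessors; structure I/O
  (Molfile V2000/XYZ, bond perception); the placement engine; constrained
  relaxation; alignment/RMSD metrics; energy bookkeeping; descriptors and
  the gap model; fixture generators.
- `tests/testthat/` — unit, property and acceptance tests with
  independent oracles (finite differences, brute-force rotation grids,
  permutation enumeration).
- `vignettes/scaffold-functionalization.Rmd` — the methods vignette:
  model, conventions, numerical choices, limitations.
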