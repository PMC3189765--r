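---
title: "Methods: field-based 3D-QSAR and common-feature pharmacophores in qsar3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: field-based 3D-QSAR and common-feature pharmacophores in qsar3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and assumptions

`qsar3d` models the activity of a *congeneric series*: compounds sharing
one rigid scaffold, differing by substituents at a few positions.  Under
that assumption a common 3D frame exists (the scaffold), activity
differences are attributable to what the substituents project into the
surrounding space, and a linear model on probe-field values sampled on a
lattice is a sensible hypothesis class.  Nothing in the package attempts
receptor modelling, docking, tautomer or protonation enumeration, or
flexible (torsional) alignment; input 3D coordinates are taken as given,
with no energy minimization, so field values are reproducible from the
structure file alone.

# Molecular preparation

**Partial charges** are iterative Gasteiger (PEOE) charges with the
classical published parameter set: electronegativity
$\chi_i(q) = a_i + b_i q + c_i q^2$ by element and hybridization, charge
transferred across each bond damped by $0.5^n$ at iteration $n$, hydrogen
cation electronegativity 20.02.  Iteration runs to convergence (largest
update below $10^{-8}$, at most 64 iterations) rather than a fixed small
count, so results are insensitive to the stopping rule at far below test
tolerances; charges start from the formal charges and total charge is
conserved exactly.  Some legacy implementations add a Hückel π-charge
term; its recipe is not published in a reproducible form, so the package
deliberately uses pure PEOE and documents that choice.

**Per-atom parameters** come from fixed in-repo tables for H, C, N, O, F,
S, Cl, Br, I: van der Waals radii and Lennard-Jones well depths of the
common general-purpose force-field magnitude, and an atomic-contribution
logP (aromatic carbon distinguished from aliphatic; hydrogens contribute
through the heavy atom they are bonded to).  The logP sum doubles as the
`ClogP` extra descriptor and, united-atom style, as the CoMSIA
hydrophobicity property.  An element outside the table is a hard error:
for a field-based method a silent default radius would corrupt results
invisibly.

**Donor/acceptor typing** is rule-based: a donor is N or O with at least
one bonded hydrogen; an acceptor is N or O with non-positive formal
charge.  Aromaticity is perceived from explicit aromatic bonds (order 4)
or Kekulé alternation in 5–7-membered rings; hybridization follows bond
orders.  These intentionally simple rules are exact for the chemistry the
package generates and tests; exotic heterocycles may need manual flags.

# Alignment

The scaffold is described by a small SMILES-like query (elements,
aromatic lowercase atoms, branches, ring closures, explicit bond orders;
unspecified bonds match any order).  Matching uses element-constrained
subgraph isomorphism (igraph's LAD solver with per-atom candidate
domains, non-induced).  The template must match as a unique atom set;
among molecule matches — including automorphic re-orderings — the one
minimizing the superposition RMSD wins, ties broken by lowest
lexicographic atom-index order, so alignment is deterministic.
Superposition itself is the closed-form Kabsch solution: SVD of the
cross-covariance, determinant-corrected so the rotation is always proper
(no reflections), with an explicit error for fewer than three mapped
atoms or collinear geometry (second singular value below $10^{-8}$ of the
largest).

# Lattice fields

The lattice is the union bounding box of all aligned atoms expanded by a
4 Å margin, discretized at 2.0 Å (both configurable; the spacing default
is the standard coarse setting at which lattice-field QSAR is usually
run, and the margin guarantees the probe samples the solvent-facing side
of every substituent).

**CoMFA.**  Steric: Lennard-Jones 12–6 with
$r_{min,i} = r_{vdw,i} + r_{probe}$ and
$\varepsilon = \sqrt{\varepsilon_i\,\varepsilon_{probe}}$ (sp³ carbon
probe, 1.70 Å / 0.1094 kcal/mol), clamped to ±30 kcal/mol.
Electrostatic: $332.17\,q_i q_{probe}/(D(r)\,r)$ with $D(r)=r$ by default
(a constant-dielectric mode sits behind a switch).  A grid point whose
unclamped steric energy reaches the truncation is a *clash* point: its
electrostatic value is undefined there and is mean-filled per column from
the training rows when the descriptor matrix is assembled — test rows
never contribute to the fill, so no information leaks.

**CoMSIA.**  $A_k(q) = \sum_i \omega_{probe,k}\,\omega_{ik}
e^{-\alpha r_{iq}^2}$ with $\alpha = 0.3$ and a probe of radius 1 Å and
value +1 in every channel.  The positive sign convention of the original
similarity-index formulation is used; a global sign flip is immaterial to
the regression.  Steric $\omega = r_{vdw}^3$, electrostatic = partial
charge, hydrophobic = the atomic logP contribution, donor/acceptor = 0/1
flags.

# Descriptors, PLS and validation

Columns are filtered by the *minimum sigma* convention: a lattice column
is dropped when its standard deviation over the training rows falls below
1.0 (field units); extra descriptors such as ClogP are exempt.  Block
scaling (`comfa_std`) divides each field block by its pooled standard
deviation so blocks contribute equal total variance, and scales extras to
unit variance; whether the extra descriptor deserves a different block
weight is genuinely open — the package exposes it but defaults to
weight 1.

PLS is NIPALS (PLS1): components are extracted from centered data, the
scores come out mutually orthogonal, and coefficients are back-transformed
to raw descriptor units for every component count, so the model can be
interrogated at any depth up to the fitted one.  Leave-one-out
cross-validation **recomputes filtering and scaling inside every fold**;
this is the conservative, leakage-free reading of a protocol that legacy
software leaves unspecified.  Reported statistics:

* $Q^2(c) = 1 - \mathrm{PRESS}(c)/\sum(y-\bar y)^2$, with $\bar y$ the
  full training mean;
* $\mathrm{SEP}(c) = \sqrt{\mathrm{PRESS}(c)/(n-c-1)}$ and
  $\mathrm{SEE} = \sqrt{\mathrm{RSS}/(n-c-1)}$ — the $n-c-1$ denominator
  is the convention that reproduces the published F values this package
  checks itself against;
* $F = [R^2/(1-R^2)]\cdot[(n-c-1)/c]$, reported as `Inf` for an exact fit;
* OPN = $\arg\max_c Q^2(c)$, ties to the smaller count;
* $r^2_{pred} = 1 - \mathrm{PRESS}_{test}/\mathrm{SD}$, deviations of the
  test compounds taken about the *training* mean;
* field contributions $\propto \sum_{j \in block} |b_j|\,s_j$, identical
  whether computed on raw or scaled units.

The stratified splitter orders compounds by activity, cuts them into
`n_test` contiguous bins and draws one test compound per bin, so the test
set spans the activity range — the property a hand-picked test set is
usually chosen for — while remaining seeded and reproducible.

# Contour maps

The `stdev*coeff` grid is $s_j b_j$ per retained lattice column (zero for
masked columns).  The conventional "80 % favored / 20 % disfavored"
display levels are interpreted as linear-interpolation quantiles of the
nonzero grid values; the legacy definition of "contribution level" is
display-convention dependent and unpublished, so the quantile reading is
fixed and documented here.  Grids export as Gaussian cube (z-fastest
voxel stream, levels recorded in the header comment) or OpenDX text.

# Pharmacophore search

Features: donor heavy atoms (HD) and acceptor heavy atoms (HA); donor
sites (DS) projected 2.9 Å along each donor–H vector and acceptor sites
(AS) 2.9 Å along the lone-pair bisector (skipped when the bonding
environment is symmetric — direction magnitude below $10^{-3}$, far above
coordinate round-off, so file round-trips cannot flip the decision);
aromatic ring centroids (AR); centroids of connected clusters of ≥ 3
low-polarity heavy atoms, |q| < 0.2, C or halogen (HP); and positive or
protonatable basic nitrogen (PN).  The 2.9 Å projection is the idealized
hydrogen-bond length.

Conformers come from seeded stochastic torsion sampling of acyclic single
bonds (up to 50 trials), scored by a clash-dominated repulsive term,
energy-sorted and diversity-pruned: a conformer whose sorted
feature-distance profile has continuous Tanimoto ≥ 0.6 to an already-kept
one counts as a duplicate; seven survive by default.  Rigid molecules
yield exactly one conformer.

The search pairs same-kind features of the reference and each other
molecule into a correspondence graph whose edges demand pairwise distance
agreement within **twice** the tolerance (each point may move by the
tolerance); maximal cliques (igraph's pivoting Bron–Kerbosch) give each
molecule's consistent subsets, and models are the maximal reference
subsets supported by every molecule, sized 4–16.  The correspondence
graph is capped at $10^4$ nodes — exceeding the cap is an explicit
"search too large" error, never silent truncation.  Because the original
distance-comparison program's score is unpublished, the package defines
and documents its own: $\mathrm{SCORE} = \mathrm{SIZE}\,(1 -
\overline{\Delta d}/\mathrm{tolerance})$, where $\overline{\Delta d}$
averages the absolute distance discrepancies of each hit molecule's best
assignment.  A perfect geometric match scores exactly SIZE.

# The synthetic benchmark

The generator stands in for a dataset that exists only as drawn images:
a rigid planar fused tricycle (aromatic bonds explicit) carrying an
exocyclic primary carboxamide — giving the series aromatic, hydrophobic,
donor and acceptor chemistry — with substituents drawn from a 14-entry
idealized-geometry library (H, alkyls to tBu, OH, OMe, NH2, halogens,
CF3, CN, Ph) at four ring positions chosen far apart and never ortho to
the amide.  Geometries use fixed bond lengths and tetrahedral/planar
angles; chains leave the ring plane and phenyl rings stand perpendicular
to it, so the worst interatomic contact across the library is mild
bay-region crowding, as in unminimized real structures.  All molecules
share the scaffold at identical coordinates, i.e. the series is
pre-aligned by construction (the alignment module is exercised by
scrambling copies with known rigid motions).

Activities are planted as a linear function of field values: cells within
6 Å of a substituent-site center (nearest site wins where regions meet)
receive weight = site sign × orientation × Gaussian taper (σ = 2 Å) /
cell standard deviation.  The orientation term aligns each cell with the
sign of its correlation to the site's dominant local field pattern
(cells tracking it weakly, |cor| < 0.5, are dropped): a substituent's
steric footprint contains both clash cells and attractive-well cells
whose values anticorrelate, and without orientation the planted
"regional effect" would partially cancel itself and the sign of the
fitted coefficient at a single cell would be ill-posed.  The default
plants on the steric field only: the Coulomb field's $1/r^2$ range makes
per-site attribution of a lattice cell genuinely ambiguous, so
electrostatic planting (available as an option) tests an attribution
convention more than it tests the model.  Endpoint I is the planted
combination rescaled to a 1.0 pIC50-unit spread around 6.5 plus
$N(0, \sigma_{noise}^2)$ noise; endpoint II is
$\rho\,(y_1 - \bar y_1) + \sqrt{1-\rho^2}\,s_{y_1}\eta$ shifted, so the
expected squared correlation equals the configured value — the
calibration is analytic in expectation and the realized correlation is
checked, not forced.

What passing the benchmark shows: the full pipeline (fields → filtering →
scaling → PLS → LOO → external prediction → contours) recovers a known
linear field signal at realistic noise (0.2 pIC50 units on a 1.0-unit
spread) and localizes it to the correct lattice regions with the correct
signs.  What it does not show: performance on real series, where the
activity is not exactly linear in field values, conformational
uncertainty and alignment error exist, measured activities carry
assay-to-assay systematic error, and the true signal may sit in field
types (electrostatics, hydrophobics) whose spatial attribution is
intrinsically diffuse.  The benchmark's problem sizes (75 compounds,
60/15 split, ~2 300 lattice columns of which ~150 survive filtering) were
chosen to mirror the scale of a typical published series while keeping a
full study run in seconds.

A note on noiseless recovery: with many more retained columns than
training rows, leave-one-out $Q^2$ of even a *noiseless* planted signal
plateaus well below 1 — the planted weight vector needs more latent
directions than a handful, and refiltering inside each fold perturbs the
retained set.  Near-perfect LOO $Q^2$ is a property of rank-limited
toy data (and is tested there), not of the full lattice benchmark; the
benchmark's own noiseless behaviour is asserted as the monotone
degradation of $Q^2$ with increasing noise.

# Numerical conventions and degenerate inputs

* Coulomb constant 332.17 kcal·Å/(mol·e²); grid point on an atom center
  is treated as a clash, never a division by zero.
* Quantile type: R's default linear interpolation (type 7), stated
  because the contour levels depend on it.
* All-zero or constant stdev*coeff grids, constant responses, zero
  test-set variance about the training mean, empty molecule sets and
  unparameterized elements are explicit errors with named causes.
* Every stochastic step (splits, substituent draws, noise, torsion
  sampling) flows from an integer seed through a scoped RNG helper that
  restores the caller's random state, so library calls never perturb a
  user's session stream and identical configurations produce
  byte-identical outputs, including written SDF/CSV/JSON.

# Limitations

Charges are σ-system Gasteiger only; the vdW/LJ and logP tables are
compact approximations adequate for relative field differences within a
series, not absolute energetics; aromatic perception covers ordinary
carbocycles and azines; MOL2 input reads ATOM/BOND records only; and the
pharmacophore score, while documented and monotone in fit quality, is not
numerically comparable to scores printed by proprietary tools.
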