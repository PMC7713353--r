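---
title: "Bi-directional target x ring-system screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-directional target x ring-system screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most approved drugs are built on a small set of recurring fused-ring
scaffolds, while a long tail of ring systems appears in only one or two
drugs.  Those rarely used ring systems are attractive starting points for
repurposing: they are synthetically proven, patent pressure on them is low,
and their 3D shape — rather than their substituents — often dominates how
they sit in a binding site.  `trscreen` implements a bi-directional screen
over a target axis (T) and a ring-system axis (R): instead of asking only
"which compound is best for my target", it simultaneously asks "which
target is best for my scaffold", because a pair that looks optimal along
one axis can be a *saddle point* — the best ligand for the target but a
poor target for the ligand — which uni-directional screening cannot
detect.

## Ring selection: descriptors

Ring systems are extracted from drug structures by deleting every acyclic
atom, partitioning what remains into connected components, and retaining
exocyclic atoms that are double-bonded to a ring atom (quinone oxygens and
ylidene bridges stay; a biphenyl-type single-bond linker splits its two
rings apart).  Three descriptors drive the selection funnel:

* **Additive van der Waals volume** (A^3/molecule):
  `V = sum(atomic contributions) - 5.92 N_B - 14.7 R_A - 3.8 R_NR`,
  with `N_B` the number of bonds including hydrogens, `R_A`/`R_NR` the
  aromatic/non-aromatic SSSR ring counts.  The per-element contributions
  are embedded in the package (`element_table()`).  The funnel keeps rings
  with `V > 140` — strictly larger than a benzene ring (81.18) — so the
  core cannot be dwarfed by its own substituents.
* **Hydrogen-bond atom counts** over fixed, versioned SMARTS lists.
  Donors are N/O bearing a hydrogen; acceptors are N/O excluding
  pyrrole-type NH and positively charged nitrogen.  The funnel keeps
  `HBA + HBD < 3`, biasing toward shape-driven binders whose polarity can
  be tuned later through substituents.
* **Frequency** of the ring system among approved drugs; only rarely used
  systems (`frequency < 3`) enter the screen.

Fragment complexity `|B^2 - A^2 + A| + H/100` (B bonds, A heavy atoms,
H heteroatoms) is computed and reported but deliberately not used as a
primary filter: it is a synthesizability prior, not a binding prior.  All
inequalities are read strictly as printed, and every boundary is a
function argument, so the conventions are documented and overridable.

## Target selection

Target selection is a declarative funnel over supplied metadata tables
(the package never queries databases): more than five deposited structures
(read strictly: at least 6), at least one carbon-containing co-crystal
ligand of molecular weight 250-800, membership in the clinical-target and
known-ligand tables (boolean columns in the input), more than 100 known
ligands, and drug-like properties of the *representative* co-crystal
ligand (MW 200-700, HBA < 5, HBD < 2).  The representative ligand is the
most frequent canonical structure among the qualifying ligands, ties
broken lexicographically; applying the criteria to a representative rather
than to every ligand was an open design choice, made configurable.
Every stage emits a `filter_report` so the funnel counts are auditable.

## Gaussian shape and color similarity

The primary T x R screen is chemo-centric: each target is represented by
its co-crystal ligands, and each ring system is compared to them with a
Gaussian shape overlay.

Each atom is a Gaussian of amplitude `p = 2.7` whose width is set so the
Gaussian integrates to the atom's hard-sphere volume (Bondi radii,
hydrogens included with their own radii).  Only first-order (pairwise)
overlaps are summed; higher-order intersection corrections are omitted.
This is the standard fast approximation for ranking; one measurable
consequence is that for strongly size-mismatched pairs the cross term can
marginally exceed the smaller self-overlap, so similarity coefficients are
clamped to [0, 1].  The pairwise overlap integrals are checked in the test
suite against an independent 3D grid-integration oracle (0.1 A spacing)
and agree to machine precision, far inside the 2 % tolerance the suite
demands.

Pharmacophore "color" features are typed points (donor, acceptor, cation,
anion, hydrophobe, ring centroid) carrying 1.0 A Gaussians; only same-type
features overlap.  Typing uses fixed graph rules equivalent to the
hydrogen-bond SMARTS set: ring features sit at SSSR centroids and
hydrophobes at the centroid of each connected all-carbon group.

Alignment starts from centroid superposition along principal axes with all
four proper sign flips, then refines each start by Nelder-Mead over the
six rigid degrees of freedom, maximizing the combined shape + color
overlap (120 iterations by default; 60 inside the pipeline, where the
molecules are small and rigid).  The procedure is deterministic for fixed
inputs, and rigid-transform recovery to a shape Tanimoto of at least 0.99
is part of the test suite.

Scores follow the conventional definitions: shape Tanimoto
`V_AB / (V_AA + V_BB - V_AB)`, its color analogue, and reference-weighted
Tversky `V_AB / (0.95 V_ref + 0.05 V_query)` (alpha configurable).
Combos (shape + color) are reported raw (0-2) and normalized (0-1); all
downstream aggregation uses the normalized scale, on which a near-identity
pair scores close to 1.

## The fused score

For one ring against one target's retained ligand overlays (pooled over
ligands and conformers; retention cutoff -0.1 on the normalized combo so
even poor comparisons are kept, capped at the top 500), the per-pair
statistics are reduced to seven factors and multiplied:

```
fused = RefTverskyCombo_Max x TanimotoCombo_Mean x RefTverskyCombo_Mean
        x TanimotoCombo_Max x RefTverskyCombo_Min x ColorTanimoto_Min
        x count
```

Multiplication is deliberately variance-sensitive — scaling any one factor
by lambda scales the score by exactly lambda — and annihilates a pair as
soon as any factor is zero (a ring-free comparison has zero color
similarity and can never win).  A pair with *no* retained comparison is
"unscored", which is distinct from a fused score of zero: unscored pairs
are excluded from the per-axis argmax so that genuinely dissimilar pairs
remain rankable, and an axis whose every pair is unscored is flagged
rather than assigned.

## The TR matrix, mutual bests and saddle points

The secondary screen is a docking-score matrix over targets x rings.
Scoring is pluggable (`tr_scorer`): the built-in `toy_shape_scorer` maps
the best shape/color complementarity of a ring to the target's reference
ligand onto a kcal/mol-like scale (lower = better), which keeps the whole
pipeline runnable and testable without a commercial engine; an external
engine attaches through a one-line subprocess contract
(`command_scorer`), and engine-specific settings (search mode, 10 A box,
vdW scaling, pose counts) ride along as an opaque configuration schema.
Rings containing elements the scorer cannot type are excluded with the
reason `missing atom types`; per-PDB scores are merged per target by the
best (most negative) score, with mean merging available.

Both axes are rank-transformed (rank 1 = most negative).  Ties are broken
deterministically by identifier, and failed or missing cells stay
unranked; an all-missing vector is flagged.  A *mutual best* is a cell
ranked 1 on both axes.  Note that a fully scored matrix always contains at
least one mutual best (the global minimum is rank 1 in its row and its
column), so the interesting output is which pair is the *best-scoring*
mutual best.  A *saddle point* is a cell ranked best along one axis but
falling in the worst `bad_quantile` (default 0.5) of the other; its
saddle index `(rank_other - 1) / (k - 1)` is 0 for a mutual best and 1 for
the very worst opposite rank.  Both detectors are validated against
brute-force scans on random matrices up to 20 x 20.

## Library enumeration

The chosen ring system, demethylated at its amine, becomes a core with a
defined N-H growth site.  Products are formed in silico as the
Buchwald-Hartwig coupling outcome with aryl/vinyl bromides: a new N-C bond
to the carbon bearing the bromide, with loss of HBr, so
`formula(product) + HBr = formula(core) + formula(reagent)` holds exactly
(this mass balance is a test invariant).  Properties per product: MW from
embedded standard atomic weights; Wildman-Crippen logP and topological
polar surface area via OpenBabel (the PSA is a topological approximation
of 3D polar surface areas printed by commercial predictors, so absolute
values differ); rotatable bonds (acyclic single bonds between non-terminal
heavy atoms, amides excluded); Lipinski rule-of-five violations; fragment
rule-of-three violations (MW > 300, logP > 3, HBD > 3, HBA > 3, rotatable
bonds > 3 — the fragment reading was chosen over Jorgensen's rule because
the latter needs predictor outputs no open tool reproduces); a protonated
amide SMARTS over ionization states; and a pan-assay interference (PAINS)
pass/fail over an embedded, versioned subset of the published catalog
covering the canonical high-frequency families (quinones, catechols,
rhodanines, hydroxyphenyl hydrazones, azo dyes, isothiazolones, alkylidene
barbiturates and relatives).  hERG and oral-absorption thresholds are
pass-through criteria applied only when an external predictor adapter
supplies values; with the default fragment rule-of-three, drug-sized
N-aryl products legitimately carry one or more violations, and the
pipeline reports that honestly rather than relaxing the rule.

Ligand efficiency is docking score divided by heavy-atom count; on the
eight reference N-aryl products (30-33 heavy atoms) this reproduces all
eight published ratios to three decimals from the printed docking scores.

## Conformers

3D embedding is delegated to a bundled Python helper running RDKit's
ETKDGv3 with an explicit per-molecule seed derived from the run seed
(kept inside 32-bit range), followed by MMFF cleanup and RMSD pruning at
0.3 A.  Repeated runs with the same seed are byte-identical, which the
native 3D builder available to the package could not guarantee.  Heavy
atoms keep their input order, so conformer coordinates map positionally
onto the molecular graph; hydrogens are appended and participate in the
shape overlay with their own radii.  Ring systems are rigid or nearly so,
hence the pipeline default of 2 conformers per ring and 1 per reference
ligand.

## What the synthetic fixtures emulate — and what they do not

The fixture generator (`fixture_spec`, `make_ring_table`,
`make_target_set`, `make_reagents`) builds every input from an embedded
vocabulary of genuine scaffolds and drug-like ligands: a ring table whose
stage survivors are planted exactly (the generator recomputes the
descriptors and refuses an infeasible plant), a target table with designed
single-criterion violations, a mutual-best plant (one target's reference
ligand *is* the drug built on the planted best ring, so the pair dominates
both axes), a saddle plant (one target's reference ligand is a ring-free
chain: every ring scores it poorly, its row-best ring is an elongated
acene, and that cell sits deep in the worst half of its column — the same
mechanism as a polyamine cofactor ligand in a real screen), and
selenium-containing rings the toy scorer cannot type, exercising the
exclusion path.  Default sizes (12 rings -> 10 -> 7 -> 5; 8 targets -> 5;
a 5 x 4 scored matrix) keep the full end-to-end run around twenty seconds
while touching every branch; they are stand-ins for scale, not for
chemistry: passing on fixtures demonstrates the machinery (parsing,
descriptors, funnels, overlay, fusion, ranking, enumeration) is correct,
not that any particular real target-ring pair will validate, and the real
349-ring table remains an optional external input.

## Numerical choices and degenerate inputs

* Ranking ties: deterministic identifier order, so heatmaps and CSVs are
  byte-stable across reruns.
* Overlay refinement: Nelder-Mead, relative tolerance 1e-8; four proper
  principal-axes starts guard against the 180-degree flip traps of planar
  molecules.
* Zero self-volume overlays raise an error; a molecule with no color
  features scores color 0 rather than erroring.
* Single-atom molecules are handled through a dedicated path (the
  R-side SDF container cannot represent them).
* Unreadable inputs fail with the offending path; malformed SMILES/SDF
  entries are skipped, warned about, and counted in a parse report.

## Known limitations

* The shape engine is a first-order open implementation: rankings are
  comparable to commercial overlay tools, absolute scores are not, and no
  attempt is made to reproduce their values bit-for-bit.
* The PAINS catalog is a curated subset, sufficient for the canonical
  interference families; a full catalog can be dropped in as a SMARTS
  list.
* The toy docking scorer is chemo-centric (ligand-shaped); it validates
  the matrix analytics, not binding energetics.
* PDB HETATM parsing perceives bonds from covalent-radius distances and
  assigns no bond orders; it is intended for extracting ligand geometry,
  not electronic structure.
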