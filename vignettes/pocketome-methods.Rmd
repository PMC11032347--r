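---
title: "Methods and design of the pocketome toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the pocketome toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketome)
```

## Scope

`pocketome` implements a pocket-centric workflow for protein–protein
interaction (PPI) structures: curation of heterodimer (HD) and
protein–ligand (PL) entries, grid-based pocket detection with buriedness
scoring and pharmacophoric typing, orthosteric/allosteric classification
of liganded pockets, a 109-component pocket descriptor vector, a
Gaussian-kernel Pocket Similarity Index (PSI), and a minimum-spanning-tree
view of the pocket collection. This vignette records the model, the
parameters that matter, and the design decisions taken where the
underlying procedure left genuine freedom.

## Curation model

Curation operates on one `structure_entry` at a time and is strictly
rule-based; every rejection names its rule so per-rule rejection files can
be written.

* X-ray entries pass iff resolution ≤ 3.5 Å and
  R~free~ − R~factor~ ≤ 0.07; cryo-EM entries iff resolution ≤ 3.0 Å and
  the Fourier shell correlation criterion value ≤ 0.143. All comparisons
  are inclusive at the boundary. NMR entries carry no resolution
  statistic, so they bypass both tests; any other method is rejected.
  Missing mandatory metadata is a rejection (`missing_metadata`), never an
  exception, so a batch run survives incomplete records.
* Heterodimers must contain exactly two protein molecules with distinct
  UniProt accessions and more than three residues each ("more than three"
  is implemented strictly, i.e. ≥ 4). Chains without a UniProt mapping
  reject the entry rather than guessing; chimeric chains are therefore
  rejected too.
* Ligands must have at least five heavy atoms, all drawn from
  C, N, O, S, P, I, Br, Cl, F, B. Deuterium counts as hydrogen (chemical
  convention), so it never contributes a heavy atom. HET codes occurring
  fewer than 10 times archive-wide (strict `< 10`) are flagged as likely
  crystallization artefacts; because rarity alone is an imperfect
  criterion, the flag set passes through a user-editable whitelist that
  models the manual inspection step of a curated pipeline.
* Alternative locations are only disqualifying at an interface: the
  altloc check takes an `interface_patch` and rejects iff a patch atom has
  a non-blank altloc character.
* Before detection, waters are always stripped; other hetero atoms are
  stripped for HD entries only, so PL entries keep their ligand. A
  pluggable `prepare_hook` (default no-op) is the seam where external
  side-chain repair or protonation tools would sit; the toolkit itself
  performs neither.

Interface distances use heavy atoms only (configurable `include_h`):
structures are protonated late and inconsistently across archives, and
heavy-atom distances keep HD and PL treatment uniform.

## Pocket detection

Detection is a cavity-grid procedure with five tunable parameters, all in
`cavity_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `step` | 1 | Å | lattice spacing; pocket volume = points × step³ |
| `boxS` | 20 | Å | edge of the cubic search box centred on the reference |
| `b` | 65 | rays | minimal buriedness to retain a point |
| `n` | 12 | neighbours | minimal retained 26-neighbours (erosion) |
| `nPTS` | 20 | points | minimal component size to count as a cavity |
| `n_rays` | 120 | – | fixed ray directions per point |
| `ray_range` | 8 | Å | ray-cast range and bulk-solvent prune |
| `clash_distance` | 2.5 | Å | protein-clash prune |

The reference that centres the box is the bound ligand in PL mode and the
partner chain in HD mode (each chain of a dimer is probed with the other
as reference). Buriedness is the number of the 120 ray directions whose
nearest intersection with a protein heavy-atom sphere (van der Waals
radii, Bondi-style table, 1.7 Å for unknown elements) lies within
`ray_range`. `n_rays = 120` makes the burial scale coincide with the
descriptor bin labels, which run from 40 (exposed) to 120 (fully buried);
`ray_range` 8 Å and `clash_distance` 2.5 Å are conventional grid-cavity
values. The ray set is a spherical Fibonacci lattice fixed at build time,
so detection is bit-reproducible across runs and platforms; the ray-cast
itself is implemented in C++ for speed, and the test suite checks it
point-by-point against a plain-R ray–sphere oracle.

Numerical conventions: all distance comparisons are inclusive (`≤`);
neighbour erosion is applied iteratively to a fixed point rather than in a
single pass (the stricter, stable reading); component ranking is by point
count with ties broken by lower centroid x, then y, then z, so cavity
identifiers are reproducible. Bins at the burial-scale edges are closed:
label `40` collects buriedness ≤ 40 and label `120` collects only
buriedness = 120, with retention governed by `b` (at default parameters
the bins below 65 of detected pockets are empty; they exist because the
descriptor schema reports the full scale).

Probe typing assigns each point the pharmacophore of its nearest protein
heavy atom within 4 Å via a residue/atom-name table (aromatic ring carbons
→ CZ, carboxylate oxygens → OD1, hydroxyls → OG, backbone/amide nitrogens
→ N, lysine/arginine cationic nitrogens → NZ, backbone and amide oxygens →
O, other carbons and sulfur → CA); points with no atom in range, or whose
nearest atom has no table entry (warned), become dummy `DU` points.

## Pocket classification

An HD pocket is *orthosteric* when at least 50% of its points are within
6 Å of a partner heavy atom. The 6 Å threshold is the interface
definition; the 50% fraction is a toolkit choice (`min_fraction`,
configurable): a quantitative rule was needed for "resides at the
interface", and a majority-of-points criterion is robust to boundary
points.

A liganded pocket in a monomer is classified after rigid-body Kabsch
superposition of the shared chain's common Cα atoms onto the heterodimer,
which expresses the partner epitope and the ligand in one frame. The
class is then:

* **PLOC** — pocket orthosteric and minimum ligand–epitope heavy-atom
  distance ≤ 1 Å (closest approach; inclusive);
* **PLONC** — pocket orthosteric, distance > 1 Å;
* **PLA** — pocket not orthosteric, regardless of distance.

PLA is implemented as *not orthosteric* without any proximity
requirement: descriptions of allosteric PPI pockets oscillate between
"near the orthosteric site" and "distinct from the interaction site", and
the non-orthosteric reading is the one that partitions the three classes
cleanly. Users who need a proximity band can filter on pocket–interface
distance themselves. A guard requires the ligand to actually occupy the
cavity (≥ 1 heavy atom within 2 Å of a cavity point); classifying a
ligand against an unrelated pocket is an error, not a silent PLA.

Known limitation: ligands that act by inducing conformational change at
the PPI surface are invisible to this purely geometric classification.

## Descriptors and processing

Each pocket yields 109 named components in a fixed global order: volume,
8 probe totals, 80 probe × burial-bin counts (the 89-block), 10
probe-aggregated burial bins T40…T120, and 10 geometric descriptors
computed from the negative image as a unit-mass point set: principal
moments of inertia PMI1 ≤ PMI2 ≤ PMI3, NPR1 = PMI1/PMI3,
NPR2 = PMI2/PMI3, radius of gyration, asphericity and spherocity index
(from the gyration-tensor eigenvalues), eccentricity
√(PMI3² − PMI1²)/PMI3 and inertial shape factor PMI2/(PMI1·PMI3). Unit
masses are used throughout (grid points have no element identity); the
mass-independent descriptors coincide with the usual cheminformatics
definitions, and the mass-dependent ones (PMIs, inertial shape factor)
are consistent within the toolkit. Collinear point sets are degenerate:
eccentricity is reported at its rod limit 1, spherocity 0, and the
inertial shape factor `NA`, with a warning.

The processing pipeline, fitted on a pocket × descriptor matrix and
reusable on new pockets via its stored state:

1. drop columns with zero values in strictly more than 95% of pockets;
2. log-rescale (as `log(1+x)`, which handles the many zero counts) each
   count-like column whose mean is strictly below 15% of its maximum and
   whose median is strictly below 65% of its mean — the high-dynamic-range,
   right-skewed case; the geometric block is excluded by default because
   its columns are not counts;
3. standardize every remaining column to zero mean and unit variance,
   using the population (1/n) variance — at dataset scale the difference
   from the sample variance is immaterial, and the population form makes
   the "variance = 1" invariant exact. Constant columns cannot be
   standardized and are dropped with a warning.

## PSI and the pocketome tree

PSI~ij~ = exp(−d~ij~²/2σ²) over Euclidean distances d in the processed
descriptor space. σ is the population standard deviation of the distances
over the N(N−1)/2 unordered pairs — the diagonal zeros are excluded, since
including them would deflate σ and sharpen every similarity; with exactly
one pair (N = 2) the spread of a single value is zero, so σ degenerates to
that distance. PSI is a similarity in (0, 1], monotone in distance (so
rankings are σ-free) and invariant to a global rescaling of the
descriptor columns. It is not a calibrated probability and no threshold
is applied to it.

The pocketome is the exact minimum spanning tree of the distance matrix
(Kruskal; weight ties broken by lexicographic pocket-ID order for
determinism). Distance, not 1 − PSI, is the edge weight: the two give the
same tree because PSI is monotone in distance, and distance avoids
coupling the tree to σ. An exact MST replaces approximate
locality-sensitive-hashing tree layouts used for very large collections;
at the scales this toolkit targets the exact tree is affordable and
strictly better. Exports: GraphML with all node annotations, and a
self-contained HTML page (inline data and script, no external resources)
with a colour-by-annotation selector. "Exposure" as a node annotation is
a toolkit definition — the fraction of cavity points with buriedness ≤ 60
— since the burial summary has no canonical formula.

## Synthetic fixtures: what they emulate, and what not

`make_toy_heterodimer()` builds chain A as a double-layer bowl of carbon
pseudo-atoms (Fibonacci-lattice layers, one residue per atom) forming a
concave pocket of the requested radius, plus an identical partner-free
bowl ~3.5 pocket radii away, and chain B as a two-layer sunflower-packed
disk plugging the main pocket mouth. The geometry was chosen from
ray-blocking solid angles so that, at the default detection parameters,
the pocket interior scores well above the buriedness threshold with and
without the plug, the detected HD cavity passes the ≥ 50% orthosteric
fraction, and a ligand placed within 1 Å of the plug still occupies the
monomer-detected cavity. `make_toy_liganded()` copies chain A and slides
a rigid six-carbon ring along the pocket axis until its minimum distance
to the partner epitope equals the requested offset to within 0.05 Å
(bisection; the distance is monotone in the slide coordinate), or seats
the ring in the far bowl for the allosteric case. All generators are pure
functions of their spec: the seed drives only a small (0.02 Å) jitter
that breaks lattice symmetry, and the session RNG state is restored.

`make_descriptor_sample()` plants Gaussian clusters with centres pairwise
`cluster_separation` apart and isotropic noise, then forces chosen
columns to zero in an exact fraction of rows — the ground truth for the
zero-filter and cluster-recovery tests. Default study conditions used in
tests and the acceptance script: 60 pockets, 10 descriptors, 2 clusters,
separation 6, noise 1.

What the fixtures deliberately do not emulate: real side-chain chemistry
(every wall atom is carbon, so real typing diversity is exercised by unit
tests with constructed residues, not by the toy complex), B-factors,
sequence content, crystallographic artefacts, and conformational change.
Passing fixture tests therefore demonstrates the correctness of the
geometry, counting and classification machinery — not the biological
accuracy of any particular threshold on real structures.

## Problem sizes and runtime choices

The test suite and acceptance script run on desk-scale instances chosen
to exercise every code path while staying fast: toy complexes of ~860
atoms and ~400-point cavities; 20 seeds per class for classification;
50 random cavities for conservation; 20 point clouds for the shape-oracle
comparison; 7-node distance matrices for exhaustive spanning-tree
enumeration (16,807 trees by Cayley's formula); 60-pocket samples for
cluster recovery. The C++ ray-cast kernel keeps one full
detection-classification cycle under a second.

## Known limitations

* The detector is a reimplementation of the cavity-grid idea, tuned by
  the published parameter table; it does not claim numerical parity with
  any proprietary pocket-detection binary.
* The probe-typing table covers the 20 standard residues plus
  element-based fallbacks; modified residues type as DU with a warning.
* The 89/10/10 descriptor partition is reconstructed from the published
  column vocabulary (volume + totals + probe × burial bins; T bins;
  geometric block). The probe-aggregated block in particular follows the
  column names (T40…T120, column sums over probes); alternative
  aggregation schemes in the literature may differ.
* Searching is confined to one `boxS` box per reference; proteins larger
  than the box are probed only around the reference, and no box tiling is
  attempted.
* PL entries are matched to heterodimers by UniProt accession only; no
  sequence-based mapping is performed.
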