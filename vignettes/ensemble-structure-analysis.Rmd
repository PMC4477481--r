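---
title: "Structural stability analysis of peptide conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural stability analysis of peptide conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdyn)
```

## Scope and model of the data

pepdyn analyses *replica conformational ensembles*: several independent
trajectories of one molecular system sharing a single topology. The design
follows the common study layout for intrinsically flexible protein domains —
the motivating case is the N-terminal signal-receiving domain (SRD) of the
NF-kB inhibitor IkBa, a ~70-residue region that carries the phosphorylation
sites Ser32/Ser36 and the ubiquitination sites Lys21/Lys22, is unresolved in
crystal structures, and is characterised instead by consensus secondary-
structure prediction followed by replica molecular-dynamics refinement in
bound (complexed with a partner) and free states.

The package deliberately stops short of molecular dynamics itself. Force
fields, integrators and solvent belong to the simulation engine; pepdyn
consumes the *frames* (as multi-model PDB, the only trajectory format it
reads and writes) and reproduces the downstream analysis layer:

1. consensus 3-state secondary-structure annotation from predictor outputs;
2. superposition geometry: RMSD series, iterative average structure,
   per-residue RMSF, minimum-distance matrices;
3. Kabsch–Sander (DSSP-style) 8-state assignment, secondary-structure
   timelines and helix-formation probabilities;
4. geometric hydrogen-bond / salt-bridge detection with per-replica
   occupancies and a persistence filter;
5. Shrake–Rupley solvent-accessible surface area, relative solvent
   accessibility (RSA) and buried/exposed classification of sites;
6. a synthetic-ensemble generator providing fully controlled inputs.

## Consensus annotation

`majority_vote()` treats each predictor as one equal vote per residue over
{H, E, C}. A state wins only with *strictly* the most votes; any tie falls
back to coil. The tie rule is deliberately conservative — a consensus should
never invent structure that half the predictors did not see — and it is why
two predictors voting H and E yield C, not H. Predictors using 8-state
alphabets must be reduced upstream (G/I into the helix class, B into the
strand class); the reader accepts only H/E/C and reports any other character
with its position.

`extract_segments()` defaults to `min_length = 4` for helices: one full
helical turn is the shortest segment worth reporting, and the shortest
helix in the motivating annotation (residues 11–14) has exactly that
length.

```{r consensus}
preds <- c("CCHHHHHHCC", "CCHHHHHHCC", "CCCHHHHHCC")
cons <- majority_vote(preds)
cons$states
extract_segments(cons, "H")
```

## Superposition geometry

`kabsch_superpose()` computes the least-squares rigid-body superposition by
SVD of the cross-covariance, with the determinant correction that forbids
reflections. Collinear selections are rejected (the rotation about the line
is undetermined). RMSF is measured *around the converged average
structure*: `average_structure()` iterates superpose-all/re-average until
the mean moves less than 1e-6 Å RMS (cap 100 iterations, warn on
non-convergence), pooling frames across replicas; each frame is then fitted
to that average and per-residue fluctuations are reported per replica plus
their mean. The fitting selection defaults to Cα of the whole protein —
the analysed studies say both "backbone" and "backbone Cα", so the
selection is configurable (`selection_spec()`) and Cα is the default.

Distance matrices use heavy atoms only and report the *mean over frames of
the per-frame minimum* inter-residue distance. The time statistic is a
choice (the figure style this reproduces does not name one); it is recorded
in the TSV header of every matrix written.

Windows ("initial half" vs "final half" of a production run) are frame-index
ranges, not times: synthetic data has no physical clock, so the 100-ns
halves of a 200-ns study map to index halves (`"first_half"`,
`"second_half"`).

## DSSP core

`assign_sse()` implements the Kabsch–Sander rules: the electrostatic
hydrogen-bond energy
`E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol (bond iff
`E < -0.5`, clamped at −9.9), n-turns for n = 3, 4, 5, minimal helices
(G/H/I) from two consecutive n-turns, parallel/antiparallel bridges,
ladders, and the beta-bulge rule linking ladders separated by at most one
residue on one strand and four on the other; turn (T) marks the interior of
any n-turn, bend (S) a Cα(i−2)/Cα(i)/Cα(i+2) kappa angle above 70°.
Overlaps resolve H > B/E > G > I > T > S.

Two conventions matter and are intentional:

* the amide hydrogen used in bond energies is always the idealised
  `H = N + 1.01 Å × unit(C_prev − O_prev)`, recomputed per frame — the
  original convention, which also makes assignments independent of whether a
  trajectory stores hydrogens. `place_amide_hydrogens()`, by contrast,
  only *adds* atoms and never moves an existing H.
* chain breaks (`|C(i)−N(i+1)| > 2.5 Å`) terminate all pattern windows, so
  multi-chain fixtures cannot form spurious inter-chain turns; inter-chain
  bridges (real sheets) remain possible.

Helix-formation probability counts state H only by default: 3_10- and
pi-helical interludes are chemically distinct and the analyses this
reproduces treat them as such. The set is a parameter
(`helix_probability(..., helix_states = c("H","G"))`) for users who want the
broader helix class. Per-replica occupancies and the frame-weighted pooled
occupancy are both reported, since either pooling convention appears in
published probability plots.

```{r dssp}
helix <- build_peptide(strrep("A", 12))
paste(assign_sse(helix$xyz, helix), collapse = "")
```

## Contacts and persistence

Hydrogen bonds use the geometric criterion donor–acceptor ≤ 3.5 Å and
H–D–A angle ≤ 30° — the convention of the MD tooling family the motivating
study used, since the study itself states no criterion; both cutoffs are
parameters and are echoed in every report header. Donors are backbone
amides plus the standard side-chain donor atoms; side-chain donors without
an explicit hydrogen fall back to distance-only and the output flags them.
Salt bridges use the Barlow–Thornton style 4.0 Å cutoff between carboxylate
oxygens (Asp/Glu) and basic nitrogens (Lys/Arg); histidine is excluded by
default because the interface tables this mirrors list only Lys/Arg
partners (`include_his = TRUE` restores it).

Occupancy is bookkept at residue-pair level (union of atom-level bonds),
matching published interface tables. The persistence filter keeps a contact
iff its occupancy exceeds `min_occupancy` (default 0.10, *strictly* — an
occupancy of exactly 10% fails) in at least `min_replicas` (default 2)
replicas. Raising either criterion can only shrink the persistent set, a
property the tests exercise.

## Solvent accessibility

`shrake_rupley()` places a deterministic golden-spiral lattice (default 960
points) on each atom's probe-expanded sphere (probe 1.4 Å; radii C 1.70,
N 1.55, O 1.52, S 1.80, H 1.20 Å) and counts points outside all neighbour
spheres. Hydrogens, when present, contribute with r = 1.2 Å rather than
being folded into heavy-atom radii; the report headers state the radii,
probe and point count. The deterministic lattice makes results bit-stable;
its cost is that rotation invariance holds only to quadrature error
(~0.2–0.5% at 960 points — the convergence test doubles the lattice and
requires < 0.5% total change).

RSA divides residue SASA by its maximal exposure in an extended Gly-X-Gly
tripeptide (Miller et al. 1987 scale, e.g. Ser 122 Å², Lys 211 Å²). The
scale ships as data rather than being recomputed, which keeps RSA
arithmetic exactly reproducible against published tables; whole-residue
SASA (not side-chain-only) is used because the published SASA/RSA ratios
are consistent with the whole-residue convention. Burial uses a strict
`RSA < 20%` threshold, so exactly 20% is exposed.

```{r rsa}
rsa(61.2, "SER")          # bound-state Ser32 -> 50.2 %
classify_burial(rsa(11.3, "SER"))  # free-state Ser36
```

## The synthetic generator

The generator produces every fixture the pipeline needs, with ground truth
known by construction:

* `build_peptide()` — ideal-geometry peptides by internal-coordinate (NeRF)
  construction (N–CA 1.458, CA–C 1.525, C–N 1.329 Å, omega 180°; presets
  alpha −57/−47 and extended −120/+120). Side chains are a CB pseudo-atom
  except Ser (OG), Lys (full chain to NZ) and Glu/Asp (carboxylates) — the
  residues that accessibility and contact analyses need real chemistry for.
  (The acidic side chains go beyond the minimal Ser/Lys plan precisely so
  salt-bridge fixtures have chemically correct partners.)
* `helix_coil_ensemble()` — per frame, each designated segment adopts the
  helix preset with its designed probability, otherwise coil with phi/psi
  drawn uniformly from a broad coil basin (phi −150..−60, psi 60..170,
  chosen so coil frames can never satisfy helix patterns); residues outside
  segments are always coil; iid Gaussian noise (default sigma 0.1 Å per
  axis) is added everywhere. The default jitter is coordinate-noise scale,
  not full thermal motion: the conformational signal is meant to come from
  helix/coil switching, not from the jitter. Helix occupancies are
  *sampled* (Bernoulli per segment per frame) and the realised counts are
  recorded in the manifest, so statistical recovery can be tested against
  both the design and the realisation.
* `contact_complex_ensemble()` — two fully-extended chains whose designed
  interface contacts switch between bonding geometry (2.9 Å, 5° off the
  carbonyl axis) and a 6 Å displaced "off" pose following *exact
  deterministic interleaved schedules*. Occupancies are exact rationals, so
  persistence-filter outcomes are analytic — deliberately the opposite
  regime from the sampled helix occupancies. Because the schedules are
  deterministic, this generator takes no RNG seed. One designed
  lysine–glutamate salt bridge is, chemically, also a donor–acceptor
  hydrogen bond; the detectors agree and the fixtures embrace rather than
  hide this.

What the generator does *not* emulate: force-field energetics, solvent,
correlated backbone motion, side-chain rotamer dynamics, or realistic
transition kinetics (frames are independent draws). Tests passing on these
ensembles therefore validate the *analysis operators* — estimator
correctness, filter semantics, geometric invariances — not the physics of
any real trajectory.

## Bound-vs-free contrast conditions

The contrast experiment generates a rigid helical 70-mer in two states with
the free state noisier. The noise offset is expressed in expected-RMSF
units: for iid per-axis noise sigma, RMSF = sigma·sqrt(3), so the free
state uses `sigma_free = sigma_bound + 1/sqrt(3)` to design a 1 Å RMSF
offset — the qualitative analogue of the published observation that free-
state fluctuations run about 1 Å above the bound state. Superposition
absorbs a small part of the fluctuation (about 6/(3N) of the variance for N
fitted atoms, ~1.5% in RMSF here), which is far inside the 20% acceptance
band.

## Problem sizes and determinism

The shipped tests and the acceptance script use: a conformer battery of 4
ideal conformers × 51 frames (ideal + 50 noisy variants at sigma 0.15 Å)
for DSSP cross-checking; 3 replicas × 2000 frames of a 70-residue peptide
with designed occupancies {0, 0.25, 0.5, 0.75, 1} for occupancy recovery
(recovery is evaluated at segment-centre residues, where helix assignment
is unambiguous; segment edges are intrinsically soft in any H-bond-based
assignment); 200-frame schedules for persistence (exact rationals); and
3 × 200 frames per state for the flexibility contrast. These sizes put
binomial sampling error well below the tolerances being tested while
keeping a full run in the minutes range on one CPU.

All randomness flows from explicit seeds (replicas get independent
substreams derived from the master seed), generated PDB output is
byte-stable, and every report carries the configuration hash and the
criteria that produced it.

## Known limitations

* The DSSP core omits the "best two H-bonds per residue" pruning of the
  original program; on clean and mildly noisy conformers this costs well
  under 1% agreement with a reference implementation, concentrated at
  strand edges.
* Multi-model PDB is the only trajectory format; binary formats (XTC/DCD)
  are out of scope by design (text-only, diffable artifacts).
* SASA uses Shrake–Rupley quadrature, not an analytic (Lee–Richards slice)
  method; accuracy is bounded by the lattice (~1% per atom at 960 points).
* The hydrogen-bond detector trusts residue/atom nomenclature (PDB v3
  names) for its donor/acceptor chemistry; exotic residues fall outside the
  tables and are treated as non-donors.
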