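---
title: "Assembling and validating phage virion models from predicted subcomplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and validating phage virion models from predicted subcomplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagebuilder)
```

## The problem

A tailed phage virion is a chain of ring-shaped protein machines: the
icosahedral capsid with its hexameric and pentameric capsomers, a
dodecameric portal replacing one penton, a dodecameric adaptor and
hexameric stopper closing the DNA channel (the "neck"), a tail
terminator, a long tube of stacked major-tail-protein (MTP) hexamers,
and the baseplate (distal tail protein hexamer, tail-associated lysin
trimer, upper baseplate and receptor-binding proteins). Structure
predictors handle the individual subcomplexes well but cap a single
prediction at a few thousand residues, so a complete virion model has to
be *assembled* from overlapping predictions and then *validated*. This
package implements that post-prediction stage as reusable, tested code.
Running the predictor itself, homology searching, and biological
interpretation are out of scope; predictions are consumed as coordinate
files with per-residue confidence in the B-factor column.

## Confidence gating

**Model.** Predictors emit a per-residue pLDDT score (0–100), written
uniformly across a residue's atoms in the B-factor field, and an N×N
predicted-aligned-error (PAE) matrix whose off-diagonal chain blocks
score inter-chain placement confidence.

**Gate.** A model is accepted when every residue of its *confidently
folded regions* reaches the pLDDT threshold (default 70; 80 is offered
as the stricter literature gate). Loop and terminal residues below
threshold are flagged but not fatal — they rarely affect the fold.

**Operationalizing "folded".** There is no universal definition of a
folded region in a predicted model, so the package uses the confidence
profile itself: a residue is in the folded mask when its smoothed pLDDT
(centered running mean, window 5, edge-truncated) reaches the threshold
within a run of at least `min_run = 8` residues. Both knobs are exposed
and documented. One consequence needs care: under a mask-only rule a
model with *no* confident region would pass vacuously. We therefore also
require a minimum folded fraction (default 0.3) — a chain in which less
than a third of the residues form confident runs has simply failed
prediction and is rejected. A 30-residue helical core scored at 55
rejects for exactly this reason.

**Complex gain.** When the same chain is predicted alone and inside a
complex, the complexed profile should be at least as good. The gate
passes when the mean delta over the stand-alone folded mask is at least
−1.0 pLDDT; the slack absorbs run-to-run predictor noise without letting
a genuine confidence drop through.

**PAE.** `interchain_pae()` pools the (a,b) and (b,a) blocks and reports
mean, median and the fraction below a "confident contact" cutoff
(default 10 Å — a documented tunable; smaller is stricter).

## Rigid superposition and assembly

`kabsch()` computes the optimal proper rotation by singular value
decomposition of the weighted covariance of centered coordinate pairs,
with the determinant correction that rejects reflections — protein
chirality makes a mirror fit meaningless here. Degenerate inputs
(coincident or collinear points, under 3 pairs) raise explicit errors.
Atom pairing defaults to CA atoms matched by author residue number; when
numbering disagrees, a global Needleman–Wunsch alignment (BLOSUM62, gap
−10/−0.5, via Biostrings) recovers the correspondence.

**Graft.** The workaround for over-limit oligomers: predict a ring of
truncated subunits plus one full-length monomer, then superpose the
monomer onto each subunit over the shared residue range and keep the
placed full-length copies. A subunit missing more than 20% of the shared
range is refused by name. Inter-chain heavy-atom pairs closer than
2.4 Å among the grafted extensions are counted and reported but never
fatal, because grafted models are used without energy refinement. On a
noiseless truncation of an exact ring the graft is an exact inverse
(per-chain rmsd below 1e−8 Å); with noise, the graft rmsd reports the
noise level.

**Stack.** `extend_stack()` estimates the ring-to-ring screw generator
jointly over all adjacent ring pairs and applies it repeatedly,
reporting rise (Å) and twist (degrees) from the screw decomposition.
Ring membership is taken from the caller or inferred by a documented
heuristic: each principal axis of the chain-centroid cloud is tried, and
the one along which the centroids split into equal-size, well-separated
axial groups wins. The heuristic covers both squat stacks and tall
tubes; pathological geometries should pass `rings` explicitly.

**Compose.** Virion sections are chained by superposing each incoming
part's shared component (chain set + residue range) onto the copy
already placed, dropping the duplicated chains, and relabeling the rest
with provenance records. A junction rmsd above the gate (default 5 Å)
aborts the assembly: a bad junction would silently corrupt everything
downstream. Composition is associative in outcome — grouping of
junctions does not move the final coordinates beyond numerical noise.

## Cyclic symmetry

Rings here are Cn oligomers. The axis is seeded from the chain
centroids (the normal of their least-squares plane through the centroid
mean) and refined by Nelder–Mead over two tilt angles and two in-plane
offsets, minimizing the mean rmsd between each subunit and its
2π/n-rotated neighbor; the rotation sense orients the axis. The
refinement tolerance is 1e−14 relative on the objective, giving
axis recovery to ~1e−8 rad on ideal rings and equivariance under rigid
motion to better than 1e−6 rad. `symmetry_deviation()` regenerates an
ideal ring from subunit 1 and reports per-subunit rmsd without refit,
so a single displaced subunit shows its displacement directly. The
6-fold/3-fold symmetry mismatch at the tail tip needs no special
machinery: composition there is by superposition, not symmetry
averaging.

## Surface areas and interfaces

SASA uses the Shrake–Rupley point method: test points on each atom's
solvent sphere (vdW radius + 1.4 Å probe), counted accessible when
outside every neighbor's sphere. The point set is a deterministic
golden-section spiral, symmetrized so that it is invariant under a
two-fold rotation about z; a z-aligned C2 homodimer then yields exactly
equal per-chain buried areas rather than quadrature jitter. The default
960 points put single-sphere quadrature error well under 1%, and
doubling the count moves any area by less than 1%. Radii are a fixed
protein heavy-atom table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
Se 1.90 Å); an unknown element is a hard error, never a silent default.

Buried area is reported **per monomer**: `BSA(A) = SASA(A alone) −
SASA(A in the union)`, clamped at zero against quadrature noise. This
matches how phage interface tables relate a monomer's buried area to its
own total surface (a portal monomer burying ~14% of its surface against
its neighbors); note that some interface servers halve the two-sided sum
instead — comparisons across conventions differ by a factor of about
two. "Total surface area" means the SASA of the isolated monomer; the
percentage arithmetic in the phage literature is consistent with that
choice, and it is the stable denominator when the same monomer appears
in several complexes.

## Density maps

`simulate_map()` places an isotropic Gaussian per heavy atom, amplitude
proportional to atomic number, with sigma = 0.225 × resolution — the
width convention common to molmap-style tools; it is a documented
tunable, as no single convention is universal. Grids extend 3 sigma
beyond the model; Gaussians are evaluated to 4 sigma.

Cross-correlation is the Pearson correlation about the mean after
trilinear resampling onto the reference grid. The default *footprint*
mask keeps only voxels where the simulated map exceeds 1% of its
maximum, because negative-stain reconstructions are mostly empty box and
a global CC rewards agreeing about emptiness; the global variant is also
reported so either convention can be matched.

`fit_in_map()` refines the six rigid parameters by coordinate cycling
with shrinking steps (start 2 Å / 5°, floor 0.05 Å / 0.1°), scoring
against a single precomputed model map by interpolation and re-scoring
the final pose exactly on the experimental grid. There is deliberately
no global search: the workflow fits manually pre-placed models, and the
reported CC is never below the CC of the starting placement. The hand
flip — mirroring the map about its center plane along one axis —
reruns the whole optimization against the z-flipped map and keeps the
better CC, recording `flipped`.

## Synthetic ground truth

The generator builds what the pipeline assumes and nothing more:
idealized poly-alanine multi-helix monomers (helix rise 1.5 Å/residue,
radius 2.3 Å, ~100°/residue; N, CA, C, O, CB atoms), replicated Cn about
z — by default at a radius placing neighbor centroids 10.5 Å apart so
rings are in contact — optionally stacked into tubes with known rise and
twist. `noise_sd` is the RMS 3-D displacement per atom (components drawn
with sd `noise_sd/√3`), so 0.3 Å injected noise reads back as ~0.3 Å
rmsd in superpositions. Confidence fixtures write designed high/low
pLDDT segments (means 90/40, jitter sd 3, truncated to [0,100]) and
block-structured PAE matrices; map fixtures are simulated
reconstructions, optionally hand-flipped, with noise at a stated SNR.
Every fixture is bit-reproducible from its seed and carries a truth
record sufficient to verify any downstream metric.

What the fixtures deliberately do *not* emulate: real side chains,
sequence diversity, predictor failure modes (fragmented complexes,
hallucinated termini), map artifacts beyond Gaussian noise, or flexible
inter-domain motion. Passing tests therefore demonstrate the geometric
and statistical machinery — superposition, symmetry, areas, correlation
— not predictor behavior on real proteins. Benchmarks against deposited
predictions and experimental reconstructions are possible with the same
functions but require external data.

## Numerical choices and problem sizes

* Residue intervals are author numbering, inclusive; a length-2 vector
  is an interval, longer vectors are explicit sets.
* PDB coordinates carry 3 decimals and B-factors 2; round-trip equality
  is asserted at those precisions. Models beyond 62 chains or
  multi-character ids must use mmCIF.
* MRC maps are written mode 2 (float32) in canonical axis order; on
  read, MAPC/MAPR/MAPS permutations are honored and the origin taken
  from the ORIGIN fields, falling back to N*START × voxel.
* Ties in the flip search go to the unflipped map (strict improvement
  required), and fit optimization accepts strict improvements only, so
  re-runs are deterministic under a fixed seed.
* The test and acceptance suites run on rings of order 3–12 with 20–60
  residue monomers and maps of 15–25 Å resolution at 4–5 Å voxels —
  small enough for quick iteration, large enough that quadrature,
  clustering and optimization behave as at production sizes.

## Known limitations

* SASA is O(N · neighbors · points) in plain R; tens of thousands of
  atoms per report are comfortable, full-virion all-pairs interface
  scans are not the intended use.
* The map fitter is local; a placement more than roughly half a subunit
  off, or rotated far from the basin, needs a manual initial transform.
* Ring inference assumes rings of identical composition roughly
  perpendicular to a common axis; distorted or incomplete rings should
  be specified explicitly.
* The mmCIF writer emits a single `atom_site` loop (coordinates,
  occupancy, B, auth/label identifiers) — sufficient for round-tripping
  models, not a general mmCIF serializer.
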