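---
title: "Rigid-body assembly of multi-domain proteins: models and methods"
author: "rigidom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body assembly of multi-domain proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigidom)
```

## The problem

Structure predictors are good at individual protein domains and markedly
worse at the relative placement of several domains in one chain. rigidom
addresses the second problem as a rigid-body optimization: given 2+ domain
models in a shared full-chain residue numbering, and inter-residue spatial
restraints between domains (and/or structural templates, and/or a cryo-EM
map), find the 6-parameter pose of every domain simultaneously that
minimizes a hybrid energy, and report up to five ranked full-length models
with confidence estimates.

Each domain pose is three intrinsic Z-Y-X Euler angles applied about the
centroid of the domain's input coordinates plus a translation. Centering
the rotation on the centroid decouples the rotation from the translation,
which conditions the optimizer well; the identity pose reproduces the
input coordinates exactly, so domains supplied at a known placement have a
well-defined zero.

## Similarity metrics

All scoring is built on the TM-score kernel `1/(1 + (d/d0)^2)` with
`d0 = max(0.5, 1.24 (L-15)^(1/3) - 1.8)`. The TM-score of an aligned pair
of structures is the kernel sum, normalized by `L_norm`, maximized over
superpositions found by a fragment-seeded search: every gapless alignment
window of lengths `L_ali`, `L_ali/2` and 4 (every length from 3 upward
when the alignment has at most 24 residues, where exhaustive seeding is
essentially free) seeds a least-squares
superposition, which is refined by repeatedly re-fitting on the residues
currently within a distance cutoff (`max(d0, 4.5)` angstrom, widened until
at least three residues qualify) until the selected set stops changing.
The tests pin this search against an exhaustive every-fragment
re-implementation in plain R.

Two scores derive from it:

* **rTM-score** — the kernel sum under ONE fixed superposition: the model
  is superposed on the native using only the residues of its best-scoring
  single domain, and all residues are scored without re-fitting. A model
  with perfect domains but a wrong inter-domain orientation scores high on
  TM-score and low on rTM-score, which is exactly the quantity a domain
  assembler must optimize. By construction rTM <= TM. The underlying
  definition in the literature is in supplementary material we do not
  restate; the "superpose on the best domain" reading is isolated behind
  `r_tm_score()` so it can be swapped. It normalizes by target length
  (the open alternative, aligned length, coincides on our fixtures).
* **TM-score_h** — the harmonic mean of per-domain TM-scores against one
  template. The harmonic mean is dominated by the worst-covered domain, so
  a template must cover *all* domains to rank highly.

The structural aligner is a deliberately simplified TM-align: dynamic
programming (gap penalty -0.6) over the kernel similarity matrix
alternated with superposition re-fitting, iterated to convergence (at most
30 rounds) from a grid of gapless fragment seeds. It is not a full
TM-align replacement — no sequence term, no circular permutations — and is
validated against brute-force seeding on small toys.

## Template search

A library (directory of single-chain PDBs + index) is ranked in two
stages. The local stage aligns each domain independently (overlaps
allowed) and ranks by TM-score_h; the top 500 enter the global stage, in
which domains are aligned in chain order with template residues claimed by
earlier domains masked, run N-to-C and C-to-N with the better direction
kept. Masking can only remove alignment options, so the global score never
exceeds the local one — a property the tests assert. If the best global
hit still leaves a domain below TM-score 0.5, the domain sequence is split
into covered and uncovered runs and each run is ranked independently
(recursion capped at the domain count), merging coverage. With three or
more domains, local hits for each consecutive domain pair are also kept.
Ties break lexicographically on template id so ranking is deterministic.

Initial models place each covered domain by its alignment superposition;
uncovered domains are appended along the nearest placed neighbor's
centroid-to-terminus direction at a radius-of-gyration offset. Because
independently aligned regions can collide, a sliding step translates the
later domain of the worst-clashing pair in 1 angstrom steps (at most 30)
along the inter-centroid vector until no CA pair is closer than 3
angstrom. With no usable hits, 20 seeded perturbations of a chain-like
tandem layout (domains along +x, centroid spacing = sum of radii of
gyration + 5 angstrom) are used instead.

## The hybrid energy

All terms are evaluated on CA positions (CB-typed distance records are
accepted in files and evaluated on CA; a documented approximation at
rigid-body resolution). Defaults in parentheses; the published method does
not report weights or supplementary functional forms, so every form below
is this package's own recorded choice, kept behind its own function:

* `e_distance` (w 1.0) — Gaussian records: `w min(((d-mean)/sd)^2, 16)`;
  the cap keeps far-from-satisfied restraints from swamping the gradient.
  Distogram records: spline-interpolated `-log(p + 1e-4)` over bin centers
  (36 bins, 2-20 angstrom by default), shifted to zero at the minimum,
  flat outside the range.
* `e_contact` (w 0.5) — contacts with probability >= 0.5 pay
  `prob ((d-18)/2)^2` capped at 16 beyond 18 angstrom; 18 angstrom is the
  same cutoff used to derive contact probabilities from distograms
  (cumulative CA mass below 18 angstrom, linear interpolation inside the
  straddling bin).
* `e_clash` (w 2.0) — `max(0, 3.8 - d)^2` over inter-domain CA pairs;
  3.8 angstrom is the peptide CA-CA spacing, the natural hard-sphere
  radius for a CA trace. Intra-domain pairs are constants under rigid
  poses and excluded.
* `e_generic_contact` (w 0.1) — per consecutive domain pair, counts CA
  pairs with d in [4.5, 8] angstrom (a CA-scale first-contact shell) and
  rewards `-min(n, cap)/cap`, `cap = ceil(3 sqrt(min(len_i, len_j)))`
  (interface area scales roughly with the smaller partner's surface). A
  weak, saturating pull that keeps restraint-free runs from drifting
  apart without crushing domains together.
* `e_connectivity` (w 2.0) — per inter-domain segment junction with g
  missing residues, `max(0, d_term - 3.8 (g+1))^2`: a linker of g residues
  can span at most 3.8 angstrom per step. Discontinuous insertions
  contribute at both crossings.
* `e_template_profile` (w 0.5) — inter-domain CA distances between
  template-aligned residue pairs (subsampled on a deterministic stride,
  at most 25 residues per domain side) form wells `((d - d_tmpl)/2)^2`
  capped at 16; hits combine as the TM-score_h-weighted mean of their
  per-hit mean well, so a marginal template cannot outvote a good one.
* `e_orientation` (w 0.5) — trRosetta-convention inter-residue angles on
  CB frames (virtual CB from N/CA/C where needed), each contributing
  `w (1 - cos(delta))`; skipped entirely for CA-only inputs.
* density term (w 1.0) — `1 - correlation` against the map, below.

The total is invariant under one common rigid motion of all domains
(density excluded), which the tests check to 1e-6. Gradients are central
finite differences with step 1e-4 (radians / angstrom) — correctness over
speed, cheap at rigid-body dimensionality (6 per domain), and any term can
be swapped without re-deriving analytics; the interface permits an
analytic drop-in. The pairwise kernels and the finite-difference loop are
compiled (Rcpp/RcppArmadillo), and every term is mirrored by an
independent plain-R double-loop oracle in the test suite (agreement 1e-9).

## Optimization

`stats::optim`'s L-BFGS-B (memory 10) minimizes over the 6 N_dom pose
vector, 200 iterations per start (iterations, not function evaluations —
the looser reading), relative energy tolerance 1e-6, from up to 20 starts
(top-10 global + top-10 local template placements, or the random
fallback). The *best iterate visited* is returned rather than the final
one: under capped potentials a line search can legitimately end uphill.
Final models are ranked by energy and de-duplicated at pairwise
rTM-score > 0.98 keeping the lower energy — near-duplicates would waste
the five output slots — and the top five are reported with per-term
energy breakdowns.

Linkers are rebuilt geometrically only: g missing residues are placed on
a circular arc between the flanking CA with uniform 3.8 angstrom chords
when the span allows, otherwise on the straight line at uniform spacing
with a "stretched" flag; linker residues are typed GLY and carry domain
id 0 in the B-factor column.

## Density-guided assembly

Maps are simulated as sums of spherical CA Gaussians with
`sigma = 0.425 resolution` (FWHM equal to the nominal resolution, a common
simulation convention), truncated at 4 sigma, on a grid padded 10 angstrom
beyond the model. The density correlation is the Pearson correlation
between the map and the model-simulated map on the same grid over voxels
where either exceeds 1e-6 of its own maximum. I/O is a minimal CCP4/MRC
mode-2 reader/writer (orthogonal, unpermuted axes only), written directly
because no installed R package reads MRC.

Stage 1 fits each domain into the map by multi-start L-BFGS on the
correlation alone: starts at the top-8 local maxima of a low-pass (1-2-1
smoothed) copy of the map times 4 seeded orientations, screened briefly
and then refined from a spatially diverse shortlist — at map resolutions
a domain's density is nearly symmetric, so near-degenerate flipped fits
must survive screening or secondary blobs are starved. Stage 2 combines
the per-domain top poses (diverse in position *and* orientation, at most
16 combinations, discarding combinations that put two domains on the same
blob — fitted centroids closer than 0.55 of their summed radii of
gyration, with the best-correlation combination as fallback) and runs the
full hybrid optimization with the density term added; models are ranked
by correlation, ties by energy. The pipeline deliberately ends after this
rigid-body stage: flexible (atomic/segment-level) refinement is out of
scope.

## Confidence (eTM-score / eRMSD)

Without a native, accuracy is estimated from what the run knows:

```
etm   = clamp(0.25 best_tm_h + 0.25 restraint_satisfaction
              + 0.2 convergence + 0.3 mean(domain_conf), 0, 1)
ermsd = d0(L) sqrt(max(0, 1/etm - 1))
```

Restraint satisfaction is the fraction of distance restraints within 2 sd
(Gaussian) or inside the 90% highest-density bin set (distogram);
convergence is the mean pairwise rTM-score of the top-5 multi-start
models; per-domain confidences default to 0.8 and stand in for an
external per-domain accuracy estimator. A missing component enters as a
neutral 0.5. The published composite and its fitted coefficients are in
supplementary material we do not have; this linear stand-in preserves the
decision convention (eTM > 0.5 suggests a correct global fold) and the
eRMSD mapping simply inverts the TM-score kernel — a heuristic, flagged
as such in every report. The tests check ranking behaviour (models with
rTM >= 0.9 to native outscore models with rTM < 0.5), not calibration.

## Synthetic fixtures: what they do and do not show

`make_toy_domain` builds CA-only folds: 2-3 packed antiparallel ideal
helices (rise 1.5 angstrom, radius 2.3 angstrom, 100 degrees/residue)
joined by 3-residue arc turns, or compact self-avoiding 3.8 angstrom-step
walks (accepted at radius of gyration <= 0.8 x 3.8 n^0.6). Both guarantee
consecutive CA spacing in [3.6, 4.0] and non-consecutive pairs >= 3.5
angstrom. `make_toy_multidomain` places domains with seeded random
relative poses so that natives have packed interfaces (>= 10 CA pairs
within 8 angstrom per consecutive pair), no inter-domain pair under 3.8
angstrom, and satisfied connectivity — i.e. every penalty term is zero at
the native, which ties the whole test suite together. The discontinuous
mode inserts domain 2 between the two segments of domain 1 with
two-residue linker gaps at both crossings.

The default study conditions used throughout the tests and the
reproduction script: 60-residue domains; exact native-derived Gaussian
restraints with sd 1 angstrom subsampled to 25% of inter-domain pairs;
starts scrambled by up to 30 degrees / 10 angstrom per domain; 20
scrambled starts per run; 20 seeds per experiment (10 for map-fitting);
maps at 8 angstrom resolution on 2 angstrom voxels. These sizes make a
run take seconds while leaving the optimization genuinely non-convex
(scrambled starts sit well outside the native basin — the scramble test
asserts that).

What passing does *not* show: real predictor restraints are noisy,
correlated and biased, real domains deviate from rigid bodies, real
domain models carry internal error, and real maps have noise and
anisotropy. The fixtures isolate the optimizer/scoring claims from the
upstream prediction problems by construction; benchmark-scale accuracy
numbers are out of scope and are not claimed.

## Numerical choices and edge cases

Euler extraction handles gimbal lock (|cos b| ~ 0) by fixing the third
angle to zero. Kabsch superposition rejects fewer than 3 pairs and
collinear point sets; reflections are repaired through the SVD determinant
sign. The distogram spline is a natural cubic with tridiagonally solved
second derivatives. Restraint subsampling takes exactly `round(frac n)`
pairs under the given seed. The L-BFGS convergence control translates the
1e-6 energy tolerance to `factr = tol / .Machine$double.eps`. Non-finite
starting energies are jittered once (0.5 angstrom / 5 degrees, seeded)
before failing hard. Flat maps yield correlation 0 with a warning and a
deterministic degenerate ranking. All randomness flows through explicit
seed arguments; the package never touches the caller's RNG state.

## Known limitations

Domains are perfectly rigid; there is no flexible refinement, no
side-chain or full-backbone building, no multi-chain support, no mmCIF,
and templates are used only structurally (no threading). The orientation
channel needs backbone atoms and is silent on CA traces. Energy weights
are non-canonical defaults exposed in `energy_weights()`. The hydrogen
bond-network restraint channel is parsed and stored but carries no energy.
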