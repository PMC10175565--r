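---
title: "Predicting zinc binding sites from structure: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting zinc binding sites from structure: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalloc)
```

## Overview

`metalloc` locates Zn²⁺ binding sites in protein structures by two
complementary routes:

1. a **geometric predictor** driven by a probability map of coordination
   environments mined from PDB LINK records (residue scoring, clustering,
   score-weighted placement, site rescoring); and
2. a **density route**: residue-centred 8-channel voxel grids fed to a fully
   convolutional 3D segmentation network, whose per-residue probability
   boxes are averaged onto a global grid from which ions are placed by
   clustering.

Both routes are evaluated with the standard binding-site protocol
(clustered matching at 5 Å, precision, recall, mean absolute deviation,
discretized Jaccard index), and everything is testable end-to-end on
synthetic metalloproteins generated by the package itself.

## The coordination-environment probability map

Zinc in proteins is typically coordinated by Cys, His, Asp and Glu side
chains at a metal–donor distance of about 2.2 Å. A PDB `LINK` record
declares one metal–ligand linkage; collecting the amino acids linked to
each zinc and sorting their 1-letter codes alphabetically yields a
canonical *coordination environment* string (so `CHC` and `CCH` are the
same environment, `CCH`). Three filters are applied during mining:

* links to water are dropped (water positions are unreliable and cannot be
  replayed when placing ions later);
* each *distinct* residue contributes one letter, however many of its atoms
  are linked (a bidentate carboxylate is one `D`, not two);
* a zinc left with fewer than two distinct amino-acid partners emits
  nothing — single-residue contacts are weak or artifactual.

The map stores, for each environment, its count over the corpus, its
probability (count divided by the total number of observed environments —
the normalization under which a residue surrounded by *every* environment
in the map scores exactly 1), and the number of distinct source structures.
The mean and population standard deviation of the metal–donor distances are
computed from the coordinates of the retained links (typically
2.2 ± 0.2 Å on real corpora; the synthetic generator reproduces this by
construction).

## The geometric predictor

**Reference points.** Each supported residue type is represented by the
position a metal would most plausibly occupy relative to it: the donor atom
itself (Cys SG, Ser OG, Thr OG1, Tyr OH, Met SD, Lys NZ, Asn OD1, Gln OE1),
or the midpoint of two equivalent donors (His ND1/NE2, Asp OD1/OD2,
Glu OE1/OE2). Midpoint residues carry a *radius increment* equal to the
midpoint–donor distance, and every search radius involving them is enlarged
by that increment. Backbone carbonyls are not reference points: the
environment alphabet is built from side-chain letters, so backbone-only
coordination is out of reach of this predictor (a known limitation).

**Residue scoring.** From each reference point, all other reference points
within `search_radius + increment` (default 5.5 Å, about 2.5× the typical
2.2 Å coordination distance) are collected; the observed letter multiset
(own letter plus neighbours) is scored by summing the probabilities of all
map environments that are sub-multisets of it. Scores therefore live in
[0, 1], reaching 1 only in the ideal fully-surrounded case.

**Clustering and placement.** Residues scoring at least `t × max score`
(default `t = 0.5`) are grouped into connected components under the
"closer than 2 × search_radius" relation (single linkage — the natural
reading of transitive grouping-by-distance). Each cluster places one
putative site at the score-weighted centroid of its members' reference
points, which by non-negativity of the weights always lies in the convex
hull of the cluster. An isolated high scorer borrows its own score for the
nearest other reference point, so the site lands at their midpoint; this
deliberately over-generates, and the rescoring step cleans up.

**Site rescoring.** Each placed site is rescored by the compatibility of
the letters of all residues whose reference points fall within
`0.6 × search_radius` (3.3 Å by default, again enlarged by per-residue
increments — without the increments a His midpoint at ≈3.2 Å from the metal
would sit exactly at the boundary). Sites scoring zero are removed
unconditionally (they sit in empty space, the failure mode the rescoring
step exists to catch), and surviving sites below `t × max` are dropped.

## Voxelization and the segmentation network

Residue environments are painted into a 16 Å cube at 0.5 Å spacing
(32³ voxels) centred on the residue's Cα; the box centre falls midway
between voxels 16 and 17 on each axis, and values are evaluated at voxel
centres with no interpolation, which makes voxelization exactly equivariant
under lattice-preserving rotations and pins every value for reproducible
tests. Each heavy atom contributes the pair-correlation occupancy

$$v(d) = 1 - \exp\!\left(-\left(r_{\mathrm{vdw}}/d\right)^{12}\right),$$

clamped to [0, 1] with `v(0) = 1`, combined across atoms by per-voxel
maximum (sums would leave the occupancy scale). Eight boolean channels are
painted — aromatic, hydrophobic, positive ionizable, negative ionizable,
H-bond donor, H-bond acceptor, occupancy, and the metal channel — using a
deterministic name-based typing table (ring atoms of Phe/Tyr/Trp/His;
carbons bonded only to C/H; Lys/Arg head groups; carboxylates; N–H/O–H
bearers; backbone and side-chain acceptors). The target grid paints only
the zinc ions (r_vdw 1.39 Å) with the same function and binarizes at 0.05,
giving a small blob of 1-voxels (radius ≈ 1.78 Å) around each ion. At
inference no metal is present and the metal channel is zero.

The network is a six-layer fully convolutional stack mapping
(32,32,32,8) → (32,32,32,1): 3-voxel (1.5 Å) filters everywhere except the
fifth layer, which uses a single wide 16-voxel (8 Å) filter to aggregate
long-range context; zero padding preserves the spatial size; ReLU
nonlinearities, dropout (p = 0.1) between layers 5 and 6, and a final
sigmoid yielding a per-voxel zinc probability. Channel widths are not part
of the architecture contract and default to a deliberately small profile
(8→6→4→4→2→2→1) chosen so the stack trains on a single CPU; the
convolution forward/backward kernels are compiled (Rcpp) and verified
against a naive R convolution and finite-difference gradients. Training
uses binary cross-entropy with AdaDelta (lr 0.5, per-epoch step decay
γ = 0.9, batch size 150, 12 epochs as defaults). The package trains this
network only at smoke scale — enough to show the loss falls on a small
synthetic set and that a single example can be overfit to a discretized
Jaccard ≥ 0.5 — it makes no claim of reproducing a production model's
accuracy. For long single-example overfitting runs the step decay is
disabled (γ = 1): with per-epoch decay over hundreds of epochs the
learning rate underflows to ~10⁻⁶ and optimisation stalls long before the
capacity limit is reached.

## Grid averaging and ion placement

Whole-protein predictions voxelize the Cys/His/Asp/Glu residues (nearly
every zinc site has one close by), predict each box independently and
average the boxes on a global 0.5 Å grid spanning their bounding box. Each
box centre is snapped to the global lattice — a shift of at most a quarter
voxel per axis — so every box voxel coincides exactly with a global grid
point and the 0.25 Å merge radius is realized as nearest-lattice-point
assignment. Without the snap, boxes centred on arbitrary Cα positions sit
on incommensurate lattices and roughly half the global voxels would
receive no contribution at all, leaving speckle holes in the density.
Voxels covered by no box report value 0 with count 0.

Ions are placed by thresholding the density (default p = 0.15), clustering
the surviving voxels with average-linkage agglomerative clustering at a
7 Å distance cutoff, and placing one ion per cluster at its
probability-weighted centroid, scored by the cluster's maximum voxel
probability. Two consequences of this construction are worth noting:

* on a unimodal density the number of placed ions is non-increasing in the
  probability threshold (the superlevel set only shrinks);
* the 7 Å cutoff *by design* merges any two density supports closer than
  7 Å, so resolving di-nuclear sites a few Å apart requires both a raised
  probability threshold (to disconnect the supports) and a cluster distance
  below the ion separation. The package exposes both knobs.

## Evaluation protocol

A prediction within 5 Å of an experimental site makes that site a true
positive; multiple predictions of one site still count once; an unhit site
is a false negative. Predictions matching no site are clustered
(average linkage, 5 Å) and each cluster counts as a single false positive.
Precision is TP/(TP+FP), recall TP/(TP+FN); undefined denominators yield an
explicit `NA`, never a silent zero. The deviation statistics (MAD) collect
the distance to the nearest true site for *all* matched predictions, not
only the best per site. A prediction within 5 Å of two true sites credits
both sites and contributes its distance to the nearer one — the simplest
deterministic reading of per-site counting. Density quality is measured by
the discretized Jaccard index of the binarized predicted and true grids,
optionally after zeroing the outer voxel shells where the model sees the
box edge; an empty union scores 1 by convention (both grids agree there is
no metal), a case the protocol otherwise never exercises.

## The synthetic generator

Synthetic metalloproteins provide ground truth with controlled geometry:
donor atoms at ideal tetrahedral (or octahedral) vertices at 2.2 Å from the
metal, perturbed by isotropic Gaussian noise; full heavy-atom residues
built from idealized internal-geometry templates oriented donor-toward-
metal; one LINK record per residue–metal contact carrying the realized
distance; decoy residues scattered with no heavy atom within 6 Å of a
planted metal, so tests never depend on accidental coordination.
Three-letter motifs (e.g. `DHH`) occupy three tetrahedral vertices and
leave the fourth vacant, standing in for sites completed by solvent.
Planted sites are kept at least 20 Å apart by default — comfortably above
the 11 Å residue-clustering distance, so two true sites can never merge
into one cluster by construction (a floor near 10 Å would allow exactly
that for sites whose coordination shells face each other).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: backbone conformational context
(templates have plausible but not Ramachandran-valid backbones), crystal
contacts and symmetry mates, alternative conformations, partial occupancy,
solvent structure, and the long tail of rare coordination chemistries. The
recovery experiments demonstrate that the algorithms are implemented
correctly, not that they attain any particular accuracy on the PDB.

## Numerical choices and problem sizes

* altLoc resolution keeps the highest-occupancy conformer, ties broken by
  altLoc identifier ascending; missing occupancy defaults to 1.0.
* The atom painter truncates the pair-correlation function at `2 r_vdw`,
  where `v < 2.5 × 10⁻⁴` — invisible at the 0.05 target threshold.
* Threshold comparisons use `≥ t × max − 10⁻¹²` to keep exact-tie cases
  deterministic across platforms.
* Clustering uses `stats::hclust`/`cutree` with a height cutoff, i.e.
  merges at distance ≤ cutoff; the brute-force oracles in the test suite
  implement the same convention independently.
* The test suite and the reproduction script use desk-scale problem sizes
  chosen as the smallest that exercise every code path with comfortable
  statistical margins: 10-structure corpora with 2 sites each for recovery,
  500 sites for distance-statistics fidelity, 20 voxel environments for
  smoke training, 150 constant-rate epochs for the single-example capacity
  check.
* Recovery corpora rotate their motifs in a balanced design (each motif
  equally represented in the map). The residue filter is *relative*
  (score ≥ t × max score in the structure), so a map skewed by sampling
  noise makes the predictor discard rare-motif sites co-occurring with
  common-motif ones — the intended behaviour of the `t` parameter, but a
  property of the corpus rather than of the implementation under test.

## Known limitations

* Backbone-only and water-mediated coordination are invisible to the
  geometric route by construction.
* The network ships untrained; its value here is a correct, testable
  implementation of the architecture and training loop, with capacity
  demonstrated at smoke scale only.
* mmCIF input is not supported, and no crystal-symmetry expansion is
  performed: coordinates are used exactly as given in the file.
* The environment store for training examples is held in memory (lists of
  arrays); there is no out-of-core store.
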