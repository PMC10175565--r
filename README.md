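# metalloc

Zinc binding sites hold together roughly a tenth of all deposited protein
structures — structural Zn(Cys)₄ knuckles, catalytic Zn(His)₂(Asp/Glu)
centres, and everything in between — yet predicted or engineered structures
come without their metals. `metalloc` is an R toolkit for locating Zn²⁺
sites in protein structures, aimed at structural bioinformaticians
annotating metalloproteins and protein engineers placing metals into
designed or predicted scaffolds.

It provides two predictors and the full evaluation protocol around them:

* **Geometric prediction from a probability map.** PDB `LINK` records
  declare metal–ligand linkages; collecting each zinc's amino-acid partners
  and sorting their one-letter codes gives a canonical *coordination
  environment* (CCHH, CCCC, DHH, ...). A corpus of structures yields a
  normalized frequency table of these environments. Each residue *i* is
  then scored by summing the probabilities of all map environments
  compatible with (i.e. sub-multisets of) the letters observed within a
  5.5 Å search radius of its reference point (donor atom, or donor
  midpoint for His/Asp/Glu). High scorers are clustered, and each cluster
  places a site at

      r_site = Σᵢ scoreᵢ · rᵢ / Σᵢ scoreᵢ ,

  which is rescored within 0.6 × 5.5 Å = 3.3 Å and filtered at a relative
  threshold *t* (default 0.5).
* **Density-based placement.** Residue environments are voxelized into
  16 Å / 0.5 Å grids (32³ voxels, 8 channels: aromatic, hydrophobic,
  positive/negative ionizable, H-bond donor/acceptor, occupancy, metal)
  using the pair-correlation occupancy v(d) = 1 − exp(−(r_vdw/d)¹²). A
  fully convolutional 3D segmentation network (3-voxel filters, one wide
  16-voxel layer, sigmoid output; compiled conv kernels, AdaDelta/BCE
  training at smoke scale) predicts a per-voxel zinc probability per
  residue box; boxes are averaged on a global grid and ions are placed at
  the probability-weighted centroids of voxel clusters (p > 0.15, 7 Å
  average-linkage cutoff).
* **Evaluation.** Clustered binary matching at 5 Å (multiple hits on one
  site count once; stray predictions within 5 Å of each other count as one
  false positive), precision = TP/(TP+FP), recall = TP/(TP+FN), mean
  absolute deviation over all matched predictions, and the discretized
  Jaccard index for density quality.
* **Synthetic metalloproteins.** A seeded generator plants zinc sites with
  ideal tetrahedral/octahedral coordination at 2.2 Å, correct LINK
  records, and decoy residues, so the whole pipeline is testable without
  downloading structures.

## Worked example

Train a probability map on a small synthetic corpus, predict sites on a
held-out structure, and score the predictions against the planted ground
truth:

```r
library(metalloc)

corpus <- lapply(1:6, function(s)
  make_protein(c("CCHH", "CCCC"), n_decoys = 10, box = 45,
               seed = 100 + s)$structure)
map <- build_probability_map(corpus)
as.data.frame(map)
#>   environment count probability n_structures
#> 1        CCCC     6         0.5            6
#> 2        CCHH     6         0.5            6

stats <- link_distance_stats(corpus)
#> metal-donor distance: 2.20 +/- 0.00 A over 48 links

query <- make_protein(lapply(c("CCHH", "CCCC"), site_spec, noise_sigma = 0.1),
                      n_decoys = 15, box = 45, seed = 991)
sites <- predict_metal1d(query$structure, map)
sites[, c("x", "y", "z", "score")]
#>           x        y        z score
#> 1  8.775677 10.00992 29.94065   0.5
#> 2 30.326561 35.69383 24.52202   0.5

evaluate_predictions(sites, query$planted_sites)
#> TP 2  FP 0  FN 0  recall 1.00  MAD 0.15 A
```

Each predicted site's score is the summed probability of the map
environments compatible with its surroundings (here each site matches
exactly one of the two equally frequent motifs, hence 0.5); the MAD is the
mean distance between predicted and planted zinc positions — 0.15 Å on
this noiseless-backbone fixture.

The same pipeline is scriptable from a shell via the installed
`exec/metalloc` entry point (`synth`, `build-map`, `link-stats`,
`predict-1d`, `voxelize`, `train-smoke`, `predict-density`, `place-ions`,
`evaluate`).

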