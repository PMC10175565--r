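# Geometric predictor: reference points, compatibility scoring, clustering,
# weighted placement, rescoring and the end-to-end pipeline.

res_df <- function(resname, names, xyz, chain = "A", resseq = 1) {
  data.frame(name = names, resname = resname, chain = chain, resseq = resseq,
             icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             het = FALSE, stringsAsFactors = FALSE)
}

test_that("reference points: donor atom or donor midpoint with radius increment", {
  cys <- res_df("CYS", "SG", matrix(c(1, 0, 0), 1))
  rp <- reference_point(cys)
  expect_equal(rp$position, c(1, 0, 0))
  expect_equal(rp$increment, 0)
  expect_equal(rp$letter, "C")

  his <- res_df("HIS", c("ND1", "NE2"), rbind(c(0, 0, 0), c(2.2, 0, 0)))
  rp2 <- reference_point(his)
  expect_equal(rp2$position, c(1.1, 0, 0))
  expect_equal(rp2$increment, 1.1)

  gly <- res_df("GLY", "CA", matrix(c(0, 0, 0), 1))
  expect_error(reference_point(gly), class = "metalloc_missing_atom")
  his_broken <- res_df("HIS", "ND1", matrix(c(0, 0, 0), 1))
  expect_error(reference_point(his_broken), class = "metalloc_missing_atom")
})

test_that("compatibility score equals the sub-multiset probability sum", {
  map <- toy_map(c(HH = 0.6, CH = 0.4))
  expect_equal(compatibility_score(c("C", "H"), map), 0.4)
  expect_equal(compatibility_score(c("C", "H", "H"), map), 1.0)  # ideal case
  expect_equal(compatibility_score(character(0), map), 0)
  expect_equal(compatibility_score("C", map), 0)
})

test_that("compatibility score agrees with exhaustive enumeration on random cases", {
  set.seed(101)
  alphabet <- c("C", "H", "D", "E", "N", "Q")
  for (case in 1:100) {
    n_env <- sample(1:8, 1)
    envs <- unique(vapply(seq_len(n_env), function(i) {
      paste(sort(sample(alphabet, sample(2:4, 1), replace = TRUE)), collapse = "")
    }, character(1)))
    w <- runif(length(envs)); w <- w / sum(w)
    map <- data.frame(environment = envs, count = 1L, probability = w,
                      n_structures = 1L, stringsAsFactors = FALSE)
    class(map) <- c("probability_map", "data.frame")
    observed <- sample(alphabet, sample(0:6, 1), replace = TRUE)
    expect_equal(compatibility_score(observed, map), oracle_compat(observed, map),
                 tolerance = 1e-12)
  }
})

test_that("residue scoring searches within the enlarged radius", {
  mk_two_cys <- function(gap) {
    st <- list(id = "x", atoms = rbind(
      res_df("CYS", "SG", matrix(c(0, 0, 0), 1), resseq = 1),
      res_df("CYS", "SG", matrix(c(gap, 0, 0), 1), resseq = 2)
    ), links = NULL)
    st$atoms$serial <- seq_len(nrow(st$atoms))
    st$atoms$element <- "S"; st$atoms$occ <- 1; st$atoms$bfac <- 0; st$atoms$altloc <- ""
    class(st) <- "pdb_structure"
    st
  }
  map <- toy_map(c(CC = 1.0))
  s4 <- score_residues(mk_two_cys(4.0), map)
  expect_equal(s4$score, c(1, 1))
  s12 <- score_residues(mk_two_cys(12.0), map)
  expect_equal(s12$score, c(0, 0))
  map4 <- toy_map(c(CCHH = 1.0))
  expect_equal(score_residues(mk_two_cys(4.0), map4)$score, c(0, 0))
})

test_that("weighted placement follows the score-weighted centroid", {
  sc <- data.frame(key = c("A1", "A2"), letter = "C", x = c(0, 2), y = 0, z = 0,
                   increment = 0, score = c(1, 1), stringsAsFactors = FALSE)
  sites <- cluster_and_place(sc, metal1d_config())
  expect_equal(nrow(sites), 1)
  expect_equal(c(sites$x, sites$y, sites$z), c(1, 0, 0))

  # scores 1 and 3 at x = 0 and 4: with both retained (t = 0.25) the
  # weighted average lands at x = 3
  sc2 <- sc; sc2$score <- c(1, 3); sc2$x <- c(0, 4)
  sites2 <- cluster_and_place(sc2, metal1d_config(threshold_t = 0.25))
  expect_equal(sites2$x, 3)

  # placement matches a brute-force centroid oracle on random clusters and
  # stays inside the member bounding box (convex-hull necessary condition)
  set.seed(5)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    xyz <- matrix(runif(n * 3, 0, 4), n)   # all within 11 A -> one cluster
    w <- runif(n, 0.5, 1)
    sc3 <- data.frame(key = paste0("A", 1:n), letter = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      increment = 0, score = w, stringsAsFactors = FALSE)
    got <- cluster_and_place(sc3, metal1d_config(threshold_t = 0.5))
    keep <- w >= 0.5 * max(w)
    expected <- colSums(xyz[keep, , drop = FALSE] * w[keep]) / sum(w[keep])
    expect_equal(c(got$x, got$y, got$z), unname(expected), tolerance = 1e-10)
    expect_true(all(c(got$x, got$y, got$z) >= apply(xyz[keep, , drop = FALSE], 2, min) - 1e-9))
    expect_true(all(c(got$x, got$y, got$z) <= apply(xyz[keep, , drop = FALSE], 2, max) + 1e-9))
  }
})

test_that("an isolated high scorer is placed midway to its nearest neighbour", {
  sc <- data.frame(key = c("A1", "A2", "A3"), letter = c("C", "C", "H"),
                   x = c(0, 30, 34), y = 0, z = 0, increment = 0,
                   score = c(1.0, 0.2, 0.2), stringsAsFactors = FALSE)
  sites <- cluster_and_place(sc, metal1d_config(threshold_t = 0.5))
  # only A1 is a high scorer; nearest other reference point is A2 at x=30
  expect_equal(nrow(sites), 1)
  expect_equal(sites$x, 15)
  expect_setequal(sites$members[[1]], c("A1", "A2"))
})

test_that("site rescoring retains pocket sites and drops empty-space sites", {
  sp <- make_protein("CCCC", n_decoys = 0, seed = 31)
  st <- sp$structure
  map <- toy_map(c(CCCC = 1.0))
  cfg <- metal1d_config()
  scores <- score_residues(st, map, cfg)
  placed <- cluster_and_place(scores, cfg)
  fake <- placed[c(1, 1), ]
  fake$x[2] <- fake$x[2] + 25   # far from any residue
  rescored <- score_sites(fake, st, map, cfg)
  expect_equal(nrow(rescored), 1)
  expect_equal(rescored$score, 1.0)
  # a single site with nonzero score is always retained
  single <- score_sites(placed, st, map, cfg)
  expect_equal(nrow(single), 1)
})

test_that("end-to-end prediction recovers planted two-site proteins", {
  corpus <- lapply(1:5, function(s) {
    make_protein(lapply(c("CCCC", "CCHH"), site_spec, noise_sigma = 0.1),
                 n_decoys = 10, box = 45, seed = 500 + s)$structure
  })
  map <- build_probability_map(corpus)
  sp <- make_protein(lapply(c("CCCC", "CCHH"), site_spec, noise_sigma = 0.1),
                     n_decoys = 15, box = 45, seed = 991)
  sites <- predict_metal1d(sp$structure, map)
  expect_equal(nrow(sites), 2)
  truth <- cbind(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z)
  pred <- cbind(sites$x, sites$y, sites$z)
  for (j in 1:2) {
    expect_lt(min(sqrt(rowSums((pred - matrix(truth[j, ], nrow(pred), 3,
                                              byrow = TRUE))^2))), 1.0)
  }

  # an all-glycine chain yields nothing
  gly <- read_pdb(write_pdb_text(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 4, 0, 0)
  )))
  expect_warning(empty <- predict_metal1d(gly, map), "no supported")
  expect_equal(nrow(empty), 0)
})

test_that("site count is non-increasing in the score threshold", {
  sp <- make_protein(c("CCCC", "CCHH"), n_decoys = 20, box = 45, seed = 77)
  corpus <- lapply(1:4, function(s) make_protein(c("CCCC", "CCHH", "DHHH"),
                                                 n_decoys = 5, box = 60,
                                                 seed = 600 + s)$structure)
  map <- build_probability_map(corpus)
  counts <- vapply(c(0.25, 0.5, 0.75, 1.0), function(t) {
    nrow(predict_metal1d(sp$structure, map, metal1d_config(threshold_t = t)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("predictions are equivariant under rigid motion", {
  sp <- make_protein("CCHH", n_decoys = 10, box = 40, seed = 55)
  corpus <- lapply(1:4, function(s) make_protein("CCHH", n_decoys = 5, box = 40,
                                                 seed = 700 + s)$structure)
  map <- build_probability_map(corpus)
  set.seed(8)
  tf <- random_rigid_transform()
  st2 <- transform_structure(sp$structure, tf)
  s1 <- predict_metal1d(sp$structure, map)
  s2 <- predict_metal1d(st2, map)
  expect_equal(nrow(s1), nrow(s2))
  moved <- tf$apply(cbind(s1$x, s1$y, s1$z))
  expect_equal(unname(cbind(s2$x, s2$y, s2$z)), unname(moved), tolerance = 1e-6)
})

test_that("noiseless tetrahedral Cys4 site is recovered to sub-half-angstrom", {
  sp <- make_protein("CCCC", n_decoys = 0, seed = 13)
  map <- toy_map(c(CCCC = 1.0))
  sites <- predict_metal1d(sp$structure, map)
  expect_equal(nrow(sites), 1)
  truth <- c(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z)
  expect_lt(sqrt(sum((c(sites$x, sites$y, sites$z) - truth)^2)), 0.5)
})
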