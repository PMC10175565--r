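# Grid averaging, ion placement on probability densities and cube I/O.

test_that("a single residue's predicted box passes through averaging unchanged", {
  sp <- make_protein("DHHH", n_decoys = 0, seed = 8)
  st <- sp$structure
  # only the single Asp is selected; predictor emits a recognizable ramp
  seen <- new.env()
  pred <- function(grid) {
    seen$grid <- grid
    array(seq(0, 1, length.out = 32^3), dim = c(32, 32, 32, 1))
  }
  dens <- predict_density(NULL, st, post_config(residue_selection = "ASP"),
                          predictor = pred)
  expect_equal(dim(dens$values), c(32, 32, 32))
  expect_true(all(dens$counts == 1))
  expect_equal(as.numeric(dens$values),
               seq(0, 1, length.out = 32^3), tolerance = 1e-12)
  # the global origin coincides with the single box origin
  expect_equal(dens$origin, seen$grid$origin, tolerance = 1e-9)
})

test_that("overlapping constant boxes average their values", {
  sp <- make_protein("CCHH", n_decoys = 0, seed = 12)
  st <- sp$structure
  # His boxes predict 0.4, Cys boxes 0.2; Cys/His overlap averages to 0.3
  a <- st$atoms
  pred <- function(grid) {
    ctr <- grid$origin + (32 / 2 - 0.5) * grid$spacing
    ca <- a[a$name == "CA" & !a$het, ]
    i <- which.min((ca$x - ctr[1])^2 + (ca$y - ctr[2])^2 + (ca$z - ctr[3])^2)
    array(if (ca$resname[i] == "CYS") 0.2 else 0.4, dim = c(32, 32, 32, 1))
  }
  dens <- predict_density(NULL, st, post_config(), predictor = pred)
  vals <- unique(round(as.numeric(dens$values[dens$counts > 0]), 10))
  expect_true(all(vals >= 0.2 - 1e-9 & vals <= 0.4 + 1e-9))
  expect_true(0.3 %in% vals)   # voxels covered by one Cys and one His box
  expect_true(all(c(0.2, 0.4) %in% vals))
})

test_that("ion placement finds weighted centroids of density blobs", {
  dm <- make_density(list(list(center = c(8, 8, 8), height = 0.9, sigma = 1)),
                     origin = c(0, 0, 0), n = 33)
  sites <- place_ions(dm, post_config())
  expect_equal(nrow(sites), 1)
  expect_lt(sqrt(sum((c(sites$x, sites$y, sites$z) - c(8, 8, 8))^2)), 0.5)
  expect_equal(sites$score, 0.9, tolerance = 1e-6)

  # weighted-centroid oracle over the superlevel set
  idx <- which(dm$values > 0.15, arr.ind = TRUE)
  xyz <- (idx - 1) * 0.5
  w <- dm$values[idx]
  expect_equal(c(sites$x, sites$y, sites$z),
               unname(colSums(xyz * w) / sum(w)), tolerance = 1e-9)

  # two blobs 12 A apart with a 7 A cutoff separate into two ions
  dm2 <- make_density(list(list(center = c(6, 10, 10), height = 0.9, sigma = 1),
                           list(center = c(18, 10, 10), height = 0.7, sigma = 1)),
                      origin = c(0, 0, 0), n = c(49, 41, 41))
  sites2 <- place_ions(dm2, post_config())
  expect_equal(nrow(sites2), 2)
  expect_equal(sites2$score, c(0.9, 0.7), tolerance = 1e-6)

  # nothing above threshold -> no ions
  dim0 <- make_density(list(list(center = c(8, 8, 8), height = 0.9, sigma = 1)),
                       origin = c(0, 0, 0), n = 33)
  expect_equal(nrow(place_ions(dim0, post_config(cluster_probability_threshold = 0.95))), 0)
})

test_that("close twin peaks merge at low threshold and split at high threshold", {
  dm <- make_density(list(list(center = c(8, 8, 8), height = 0.97, sigma = 1),
                          list(center = c(12, 8, 8), height = 0.66, sigma = 1)),
                     origin = c(0, 0, 0), n = c(41, 33, 33))
  low <- place_ions(dm, post_config(cluster_probability_threshold = 0.15))
  expect_equal(nrow(low), 1)
  # at 0.5 the superlevel supports are disjoint; resolving them into two
  # ions additionally needs a cluster distance below the peak separation
  # (the default 7 A cutoff merges anything closer than 7 A by design)
  high_vox <- which(dm$values > 0.5, arr.ind = TRUE)
  x <- (high_vox[, 1] - 1) * 0.5
  expect_true(all(x < 9.5 | x > 11))   # two disjoint supports
  high <- place_ions(dm, post_config(cluster_probability_threshold = 0.5,
                                     cluster_distance_threshold = 3))
  expect_equal(nrow(high), 2)
  merged <- place_ions(dm, post_config(cluster_probability_threshold = 0.5))
  expect_equal(nrow(merged), 1)

  # on a unimodal field the count is non-increasing in the threshold
  # (splitting multi-modal supports, as above, is the documented exception)
  uni <- make_density(list(list(center = c(8, 8, 8), height = 0.9, sigma = 1)),
                      origin = c(0, 0, 0), n = 33)
  counts <- vapply(c(0.15, 0.3, 0.5, 0.7, 0.95), function(p) {
    nrow(place_ions(uni, post_config(cluster_probability_threshold = p)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 1)
  expect_equal(counts[5], 0)
})

test_that("an oracle predictor recovers every planted zinc through the full stack", {
  sp <- make_protein(c("CCHH", "CCCC"), n_decoys = 10, box = 45, seed = 33)
  st <- sp$structure
  oracle <- function(grid) voxelize_target(sp$planted_sites, grid)$values
  dens <- predict_density(NULL, st, post_config(), predictor = oracle)
  sites <- place_ions(dens, post_config())
  expect_equal(nrow(sites), 2)
  truth <- cbind(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z)
  for (j in 1:2) {
    dmin <- min(sqrt((sites$x - truth[j, 1])^2 + (sites$y - truth[j, 2])^2 +
                       (sites$z - truth[j, 3])^2))
    expect_lt(dmin, 0.5)
  }
})

test_that("density selection errors when no eligible residues exist", {
  gly <- read_pdb(write_pdb_text(c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  )))
  expect_error(predict_density(NULL, gly, post_config(),
                               predictor = function(g) array(0, c(32, 32, 32, 1))),
               "no residues")
})

test_that("cube files round-trip values, origin and spacing", {
  dm <- make_density(list(list(center = c(3, 4, 5), height = 0.8, sigma = 1.2)),
                     origin = c(1, 2, 3), n = c(9, 10, 11))
  f <- tempfile(fileext = ".cube")
  write_cube(dm, f)
  dm2 <- read_cube(f)
  expect_equal(dim(dm2$values), dim(dm$values))
  expect_equal(dm2$origin, dm$origin, tolerance = 1e-5)
  expect_equal(dm2$spacing, dm$spacing, tolerance = 1e-6)
  expect_equal(dm2$values, dm$values, tolerance = 1e-4)
})
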