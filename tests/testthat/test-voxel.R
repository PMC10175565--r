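# Channel typing, pair-correlation voxelization, target grids and balanced
# residue sampling.

test_that("atom typing follows the channel rule table", {
  ch <- assign_channels("CZ", "PHE", "C")
  expect_true(ch["aromatic"] && ch["hydrophobic"] && ch["occupancy"])
  expect_false(any(ch[c("positive_ionizable", "negative_ionizable",
                        "hbond_donor", "hbond_acceptor", "metal_chain")]))

  bn <- assign_channels("N", "ALA", "N")
  expect_true(bn["hbond_donor"] && bn["occupancy"])
  expect_false(bn["hbond_acceptor"])

  zn <- assign_channels("ZN", "ZN", "ZN", is_metal = TRUE)
  expect_true(zn["metal_chain"] && zn["occupancy"])

  asp <- assign_channels("OD1", "ASP", "O")
  expect_true(asp["negative_ionizable"] && asp["hbond_acceptor"])
  lys <- assign_channels("NZ", "LYS", "N")
  expect_true(lys["positive_ionizable"] && lys["hbond_donor"])
  expect_warning(unk <- assign_channels("X1", "XYZ", "C"), "unknown residue")
  expect_equal(sum(unk), 1)  # occupancy only
})

test_that("grids have the documented shape and the pair-correlation closed form", {
  # a lone carbon; occupancy channel must equal the closed form everywhere
  st <- read_pdb(write_pdb_text(
    pdb_atom_line(1, "CB", "ALA", "A", 1, 1.95, 0, 0)
  ))
  grid <- voxelize_environment(st, center = c(0, 0, 0))
  expect_equal(dim(grid$values), c(32, 32, 32, 8))
  expect_true(all(grid$values >= 0 & grid$values <= 1))
  ax <- lapply(1:3, function(k) grid$origin[k] + (0:31) * 0.5)
  dd <- sqrt(outer(outer((ax[[1]] - 1.95)^2, (ax[[2]] - 0)^2, "+"),
                   (ax[[3]] - 0)^2, "+"))
  oracle <- 1 - exp(-(1.70 / dd)^12)
  # the painter truncates at 2 r_vdw where v < 2.5e-4
  expect_lt(max(abs(grid$values[, , , 7] - oracle)), 3e-4)
  # exact at the voxel centre nearest the atom (inside the cutoff)
  ix <- which.min(abs(ax[[1]] - 1.95))
  iy <- which.min(abs(ax[[2]])); iz <- which.min(abs(ax[[3]]))
  expect_equal(grid$values[ix, iy, iz, 7], oracle[ix, iy, iz], tolerance = 1e-12)
  # hydrophobic channel painted identically for this atom, others empty
  expect_equal(grid$values[, , , 2], grid$values[, , , 7])
  expect_true(all(grid$values[, , , c(1, 3:6, 8)] == 0))

  # empty neighbourhood -> zero grid
  far <- voxelize_environment(st, center = c(100, 100, 100))
  expect_true(all(far$values == 0))
})

test_that("metal channel paints zinc at training time and is empty at inference", {
  sp <- make_protein("CCCC", n_decoys = 0, seed = 3)
  st <- sp$structure
  ctr <- c(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z)
  g_train <- voxelize_environment(st, center = ctr, include_metals = TRUE)
  g_inf <- voxelize_environment(st, center = ctr, include_metals = FALSE)
  expect_gt(max(g_train$values[, , , 8]), 0.9)
  expect_equal(max(g_inf$values[, , , 8]), 0)
})

test_that("target grids are binary blobs matching the thresholded closed form", {
  sp <- make_protein("CCCC", n_decoys = 0, seed = 3)
  ctr <- c(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z)
  grid <- voxelize_environment(sp$structure, center = ctr)
  tgt <- voxelize_target(sp$planted_sites, grid)
  v <- tgt$values
  expect_setequal(unique(as.numeric(v)), c(0, 1))
  # oracle: recompute v(d) > 0.05 per voxel from the closed form
  ax <- lapply(1:3, function(k) grid$origin[k] + (0:31) * 0.5)
  dd <- sqrt(outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                   (ax[[3]] - ctr[3])^2, "+"))
  oracle <- (1 - exp(-(1.39 / dd)^12)) > 0.05
  expect_equal(as.numeric(v[, , , 1]), as.numeric(oracle))
  # the 1-region radius: v(d) = 0.05 at d = 1.39 * (-log(0.95))^(-1/12) ~ 1.78 A
  expect_true(all(dd[v[, , , 1] == 1] < 1.79))

  # two zincs 4 A apart give two disjoint blobs
  two <- rbind(ctr, ctr + c(4, 0, 0))
  tgt2 <- voxelize_target(two, grid)
  ones <- which(tgt2$values[, , , 1] == 1, arr.ind = TRUE)
  pos <- sweep((ones - 1) * 0.5, 2, grid$origin, "+")
  d1 <- sqrt(rowSums(sweep(pos, 2, two[1, ])^2))
  d2 <- sqrt(rowSums(sweep(pos, 2, two[2, ])^2))
  expect_true(all(pmin(d1, d2) < 1.79))       # every 1-voxel belongs to a blob
  expect_true(all(pmax(pmin(d1, d2), 0) < 2)) # and no voxel in the gap midzone
  expect_true(min(d1) < 0.5 && min(d2) < 0.5)

  # zinc-free box is all zero
  tgt0 <- voxelize_target(matrix(numeric(0), 0, 3), grid)
  expect_true(all(tgt0$values == 0))
})

test_that("voxelization is equivariant under axis-permutation rotations", {
  sp <- make_protein("CCHH", n_decoys = 5, box = 40, seed = 19)
  st <- sp$structure
  ctr <- round(c(sp$planted_sites$x, sp$planted_sites$y, sp$planted_sites$z), 1)
  g1 <- voxelize_environment(st, center = ctr)
  # rotate atoms 90 degrees about the box-centre z axis: (x,y) -> (-y, x)
  st2 <- st
  dx <- st$atoms$x - ctr[1]; dy <- st$atoms$y - ctr[2]
  st2$atoms$x <- ctr[1] - dy
  st2$atoms$y <- ctr[2] + dx
  g2 <- voxelize_environment(st2, center = ctr)
  # grid values rotate with the atoms: g2[i,j,k] = g1[j, 33-i, k]
  rot_vals <- aperm(g1$values, c(2, 1, 3, 4))[32:1, , , , drop = FALSE]
  expect_equal(g2$values, rot_vals, tolerance = 1e-9)
})

test_that("training residue sampling is balanced, seeded and 12 A based", {
  sp <- make_protein("CCCC", n_decoys = 60, box = 60, seed = 41)
  st <- sp$structure
  samp <- sample_training_residues(st, sp$planted_sites, seed = 7)
  npos <- sum(samp$label == "positive")
  nneg <- sum(samp$label == "negative")
  expect_gt(npos, 0)
  expect_equal(npos, nneg)
  samp2 <- sample_training_residues(st, sp$planted_sites, seed = 7)
  expect_identical(samp, samp2)
  samp3 <- sample_training_residues(st, sp$planted_sites, seed = 8)
  expect_false(identical(samp$key, samp3$key))

  # distance rule: every positive CA within 12 A of a zinc
  a <- st$atoms
  ca <- a[!a$het & a$name == "CA", ]
  keys <- metalloc:::residue_key(ca$chain, ca$resseq, ca$icode)
  zn <- sp$planted_sites
  dmin <- vapply(seq_len(nrow(ca)), function(i) {
    min(sqrt((zn$x - ca$x[i])^2 + (zn$y - ca$y[i])^2 + (zn$z - ca$z[i])^2))
  }, numeric(1))
  expect_setequal(samp$key[samp$label == "positive"], keys[dmin <= 12])

  # zinc-free structure -> empty sample
  none <- sample_training_residues(st, sp$planted_sites[0, ], seed = 1)
  expect_equal(nrow(none), 0)
})
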