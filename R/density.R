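# Global-grid averaging of per-residue probability boxes and cluster-based
# ion placement on the averaged density.

#' Post-processing configuration
#'
#' @param residue_selection Residue types voxelized for whole-protein
#'   prediction (default Cys/His/Asp/Glu, the types found near almost all
#'   zinc sites).
#' @param merge_radius Distance within which box voxels are averaged onto a
#'   global grid point (default 0.25 A, i.e. nearest lattice point at 0.5 A
#'   spacing).
#' @param cluster_probability_threshold Voxels above this probability enter
#'   the placement clustering (default 0.15).
#' @param cluster_distance_threshold Agglomerative-clustering distance
#'   cutoff in Angstrom (default 7).
#' @return A list of class `post_config`.
#' @export
post_config <- function(residue_selection = c("CYS", "HIS", "ASP", "GLU"),
                        merge_radius = 0.25,
                        cluster_probability_threshold = 0.15,
                        cluster_distance_threshold = 7) {
  stopifnot(merge_radius > 0,
            cluster_probability_threshold > 0, cluster_probability_threshold < 1,
            cluster_distance_threshold > 0)
  structure(list(residue_selection = residue_selection,
                 merge_radius = merge_radius,
                 cluster_probability_threshold = cluster_probability_threshold,
                 cluster_distance_threshold = cluster_distance_threshold),
            class = "post_config")
}

#' Average per-residue probability boxes onto a global density
#'
#' Voxelizes each selected residue, runs the predictor on the box, and
#' averages the predicted boxes on a global 0.5 A grid spanning their
#' bounding box. Box centres are snapped to the global lattice (a shift of
#' at most a quarter voxel per axis), so every box voxel coincides with a
#' global grid point within the merge radius; a global voxel's value is the
#' mean of all box voxels mapping to it, or 0 (count 0) when no box covers
#' it.
#'
#' @param model A `metal3d_network` (ignored when `predictor` is given).
#' @param structure A `pdb_structure`.
#' @param post A [post_config()].
#' @param predictor Function taking a `voxel_grid` (8-channel input box)
#'   and returning the predicted `[n,n,n,1]` probability array; defaults
#'   to the network forward pass. Substituting an oracle predictor here
#'   isolates the averaging/placement plumbing from model quality.
#' @param box,spacing Box geometry passed to [voxelize_environment()].
#' @return A `density_map`: `values`, `counts`, `origin`, `spacing`.
#' @export
predict_density <- function(model, structure, post = post_config(),
                            predictor = NULL, box = 16, spacing = 0.5) {
  if (is.null(predictor)) {
    predictor <- function(grid) network_forward(model, grid)
  }
  a <- structure$atoms
  keys <- residue_key(a$chain, a$resseq, a$icode)
  sel <- !a$het & a$resname %in% post$residue_selection & a$name == "CA"
  if (!any(sel)) {
    stop("no residues of the selected types (",
         paste(post$residue_selection, collapse = ","), ") with C-alpha atoms",
         call. = FALSE)
  }
  centers <- cbind(a$x[sel], a$y[sel], a$z[sel])
  # snap box centres to the global lattice so all boxes share one grid
  centers <- round(centers / spacing) * spacing
  sel_keys <- keys[sel]

  n <- as.integer(round(box / spacing))
  half <- (n / 2 - 0.5) * spacing
  lo <- apply(centers, 2, min) - half
  hi <- apply(centers, 2, max) + half
  gn <- as.integer(round((hi - lo) / spacing)) + 1L

  sums <- array(0, dim = gn)
  counts <- array(0L, dim = gn)
  for (i in seq_len(nrow(centers))) {
    grid <- voxelize_environment(structure, center = centers[i, ], box = box,
                                 spacing = spacing, include_metals = FALSE)
    pred <- predictor(grid)
    if (inherits(pred, "voxel_grid")) pred <- pred$values
    pred <- array(pred, dim = c(n, n, n))
    off <- as.integer(round((grid$origin - lo) / spacing))
    ix <- off[1] + seq_len(n); iy <- off[2] + seq_len(n); iz <- off[3] + seq_len(n)
    sums[ix, iy, iz] <- sums[ix, iy, iz] + pred
    counts[ix, iy, iz] <- counts[ix, iy, iz] + 1L
  }
  vals <- sums
  nz <- counts > 0L
  vals[nz] <- sums[nz] / counts[nz]
  structure(list(values = vals, counts = counts, origin = lo, spacing = spacing,
                 residues = sel_keys),
            class = "density_map")
}

# average-linkage agglomerative clustering with a distance threshold;
# single point -> one cluster
.threshold_cluster <- function(xyz, threshold) {
  n <- nrow(xyz)
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(xyz), method = "average")
  stats::cutree(hc, h = threshold)
}

#' Place metal ions on a probability density
#'
#' Voxels above the probability threshold are clustered by average-linkage
#' agglomerative clustering with a distance cutoff; each cluster yields one
#' ion at the probability-weighted centroid of its voxels, scored with the
#' cluster's maximum voxel probability.
#'
#' @param density A `density_map`.
#' @param post A [post_config()] (threshold and cutoff).
#' @return A `predicted_sites` data frame (`x`, `y`, `z`, `score`,
#'   `n_voxels`), sorted by score descending.
#' @export
place_ions <- function(density, post = post_config()) {
  stopifnot(inherits(density, "density_map"))
  v <- density$values
  idx <- which(v > post$cluster_probability_threshold, arr.ind = TRUE)
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      score = numeric(), n_voxels = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("predicted_sites", "data.frame")
  if (!nrow(idx)) return(empty)
  if (nrow(idx) > 60000) {
    stop(nrow(idx), " voxels above the probability threshold; raise the ",
         "threshold before clustering", call. = FALSE)
  }
  xyz <- sweep((idx - 1) * density$spacing, 2, density$origin, "+")
  p <- v[idx]
  cl <- .threshold_cluster(xyz, post$cluster_distance_threshold)
  out <- lapply(sort(unique(cl)), function(ci) {
    m <- cl == ci
    w <- p[m]
    c(colSums(xyz[m, , drop = FALSE] * w) / sum(w), max(w), sum(m))
  })
  res <- do.call(rbind, out)
  sites <- data.frame(x = res[, 1], y = res[, 2], z = res[, 3],
                      score = res[, 4], n_voxels = as.integer(res[, 5]),
                      stringsAsFactors = FALSE)
  sites <- sites[order(-sites$score, sites$x, sites$y, sites$z), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("predicted_sites", "data.frame")
  sites
}

.bohr_per_angstrom <- 1 / 0.52917721067

#' Write a density map as a Gaussian cube file
#'
#' Standard cube layout (lengths in Bohr, z-fastest value order). No atoms
#' are written (atom count 0); the two comment lines identify the grid.
#'
#' @param density A `density_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(density, path) {
  stopifnot(inherits(density, "density_map"))
  n <- dim(density$values)
  b <- .bohr_per_angstrom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("metalloc probability density",
               "zinc probability per voxel"), con)
  # cube origin is the corner voxel centre
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", 0L,
                     density$origin[1] * b, density$origin[2] * b,
                     density$origin[3] * b), con)
  sp <- density$spacing * b
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[1], sp, 0, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[2], 0, sp, 0), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[3], 0, 0, sp), con)
  v <- density$values
  for (i in seq_len(n[1])) {
    for (j in seq_len(n[2])) {
      row <- v[i, j, ]
      chunks <- split(row, ceiling(seq_along(row) / 6))
      writeLines(vapply(chunks, function(ck) paste(sprintf("%13.5E", ck), collapse = ""),
                        character(1)), con)
    }
  }
  invisible(path)
}

#' Read a Gaussian cube file into a density map
#'
#' @param path Cube file path.
#' @return A `density_map` (counts set to 1 where values exist).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  natoms <- abs(as.integer(hdr[1]))
  origin <- as.numeric(hdr[2:4]) / .bohr_per_angstrom
  nx <- as.integer(strsplit(trimws(lines[4]), "\\s+")[[1]][1])
  ny <- as.integer(strsplit(trimws(lines[5]), "\\s+")[[1]][1])
  nz <- as.integer(strsplit(trimws(lines[6]), "\\s+")[[1]][1])
  sp <- as.numeric(strsplit(trimws(lines[4]), "\\s+")[[1]][2]) / .bohr_per_angstrom
  data_start <- 7 + natoms
  nums <- as.numeric(unlist(strsplit(trimws(lines[data_start:length(lines)]), "\\s+")))
  stopifnot(length(nums) == nx * ny * nz)
  vals <- array(0, dim = c(nx, ny, nz))
  # cube order: x slowest, z fastest
  vals[] <- aperm(array(nums, dim = c(nz, ny, nx)), c(3, 2, 1))
  structure(list(values = vals, counts = array(1L, dim = c(nx, ny, nz)),
                 origin = origin, spacing = sp),
            class = "density_map")
}
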