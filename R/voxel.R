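# 8-channel voxelization of residue-centred environments and the binary
# zinc target grids.

#' Voxel channel names
#'
#' The fixed, ordered set of 8 input channels painted onto each grid.
#'
#' @return Character vector of length 8.
#' @export
channel_names <- function() {
  c("aromatic", "hydrophobic", "positive_ionizable", "negative_ionizable",
    "hbond_donor", "hbond_acceptor", "occupancy", "metal_chain")
}

# van der Waals radii (A); standard values, fallback 1.70
.vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90,
          ZN = 1.39, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- .vdw[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# atom-typing rule tables (name-based, per residue)
.aromatic_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
# carbons bonded only to carbon/hydrogen
.hydrophobic_atoms <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = "CB",
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = "CB", LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  PRO = c("CB", "CG"), GLU = c("CB", "CG"), ASP = "CB",
  GLN = c("CB", "CG"), ASN = "CB", THR = "CG2"
)
.positive_atoms <- list(LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2"))
.negative_atoms <- list(ASP = c("OD1", "OD2", "CG"), GLU = c("OE1", "OE2", "CD"))
.donor_atoms <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ"
)
.acceptor_extra <- list(HIS = c("ND1", "NE2"), MET = "SD")

.in_table <- function(tab, resname, name) {
  atoms <- tab[[resname]]
  !is.null(atoms) && name %in% atoms
}

#' Assign voxel channels to one atom
#'
#' Deterministic name-based typing: aromatic ring atoms, aliphatic carbons,
#' ionizable groups, hydrogen-bond donors/acceptors, occupancy (every heavy
#' atom) and the metal channel. Atoms of non-standard residues type as
#' occupancy only, with a warning.
#'
#' @param name Atom name (e.g. `"CZ"`).
#' @param resname Residue 3-letter code.
#' @param element Element symbol.
#' @param is_metal Is this a metal HETATM?
#' @return Named logical vector over [channel_names()].
#' @export
assign_channels <- function(name, resname, element, is_metal = FALSE) {
  ch <- stats::setNames(logical(8), channel_names())
  ch["occupancy"] <- TRUE
  if (is_metal) {
    ch["metal_chain"] <- TRUE
    return(ch)
  }
  if (!(resname %in% standard_residues())) {
    warning("unknown residue ", resname, ": atom typed as occupancy only",
            call. = FALSE)
    return(ch)
  }
  backbone <- name %in% c("N", "CA", "C", "O", "OXT")
  ch["aromatic"] <- .in_table(.aromatic_atoms, resname, name)
  ch["hydrophobic"] <- .in_table(.hydrophobic_atoms, resname, name)
  ch["positive_ionizable"] <- .in_table(.positive_atoms, resname, name)
  ch["negative_ionizable"] <- .in_table(.negative_atoms, resname, name)
  ch["hbond_donor"] <- name == "N" || .in_table(.donor_atoms, resname, name)
  ch["hbond_acceptor"] <- name %in% c("O", "OXT") ||
    (element == "O" && !backbone) || .in_table(.acceptor_extra, resname, name)
  ch
}

# pair-correlation occupancy: v(d) = 1 - exp(-(r/d)^12), v(0) = 1
pair_correlation <- function(d, r) {
  v <- 1 - exp(-(r / pmax(d, 1e-9))^12)
  v[d <= 0] <- 1
  pmin(pmax(v, 0), 1)
}

# paint a set of atoms onto one channel array via max-combination
.paint <- function(vals, ax, atoms_xyz, radii) {
  cutoff_mult <- 2.0   # v(2r) ~ 2.4e-4, negligible beyond
  for (i in seq_len(nrow(atoms_xyz))) {
    p <- atoms_xyz[i, ]
    r <- radii[i]
    cut <- cutoff_mult * r
    ix <- which(abs(ax[[1]] - p[1]) <= cut)
    iy <- which(abs(ax[[2]] - p[2]) <= cut)
    iz <- which(abs(ax[[3]] - p[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[[1]][ix] - p[1])^2
    dy2 <- (ax[[2]][iy] - p[2])^2
    dz2 <- (ax[[3]][iz] - p[3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    v <- pair_correlation(d, r)
    vals[ix, iy, iz] <- pmax(vals[ix, iy, iz], v)
  }
  vals
}

#' Voxelize a residue-centred environment
#'
#' Builds the 8-channel cubic grid around a residue's C-alpha: an optional
#' uniform random rotation is applied about the centre, then each heavy
#' atom paints its channels with the pair-correlation occupancy
#' `v(d) = 1 - exp(-(r_vdw/d)^12)` evaluated at voxel centres, combined by
#' per-voxel maximum. Hydrogens and waters are excluded; metals paint the
#' metal channel only when `include_metals` is `TRUE` (training-style
#' input).
#'
#' @param structure A `pdb_structure`.
#' @param center_residue Residue key (see [read_pdb()]) of the centre
#'   residue, or `NULL` when `center` is given directly.
#' @param box Box edge length in Angstrom (default 16).
#' @param spacing Voxel spacing in Angstrom (default 0.5).
#' @param center Explicit box centre (xyz), overrides the C-alpha.
#' @param rotate Apply a random rotation (consumes RNG)? Default `FALSE`.
#' @param include_metals Paint metal HETATMs into the metal channel?
#'   Default `TRUE`; at inference no metal is present and the channel is
#'   zero.
#' @return A `voxel_grid`: list with `values` (array `[nx, ny, nz, 8]`),
#'   `origin` (centre of the corner voxel), `spacing`, `channels`.
#' @export
voxelize_environment <- function(structure, center_residue = NULL, box = 16,
                                 spacing = 0.5, center = NULL, rotate = FALSE,
                                 include_metals = TRUE) {
  a <- structure$atoms
  if (is.null(center)) {
    stopifnot(!is.null(center_residue))
    keys <- residue_key(a$chain, a$resseq, a$icode)
    ca <- which(keys == center_residue & a$name == "CA" & !a$het)
    if (!length(ca)) stop("centre residue ", center_residue, " has no C-alpha atom",
                          call. = FALSE)
    center <- c(a$x[ca[1]], a$y[ca[1]], a$z[ca[1]])
  }
  n <- as.integer(round(box / spacing))
  # origin = centre of the corner voxel; the box centre falls midway
  # between voxels n/2 and n/2+1 on each axis
  origin <- center - (n / 2 - 0.5) * spacing
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(n) - 1) * spacing)

  a <- a[!(a$element %in% c("H", "D")) & !(a$resname %in% .water_names), , drop = FALSE]
  xyz <- cbind(a$x, a$y, a$z)
  if (rotate && nrow(xyz)) {
    rot <- random_rotation()
    xyz <- t(rot %*% (t(xyz) - center)) + matrix(center, nrow(xyz), 3, byrow = TRUE)
  }
  margin <- 2 * 2.0   # atoms beyond any paint cutoff from the box are skipped
  inside <- xyz[, 1] >= origin[1] - margin & xyz[, 1] <= ax[[1]][n] + margin &
    xyz[, 2] >= origin[2] - margin & xyz[, 2] <= ax[[2]][n] + margin &
    xyz[, 3] >= origin[3] - margin & xyz[, 3] <= ax[[3]][n] + margin
  a <- a[inside, , drop = FALSE]
  xyz <- xyz[inside, , drop = FALSE]

  vals <- array(0, dim = c(n, n, n, 8))
  if (nrow(a)) {
    is_metal <- a$het & a$resname == "ZN"
    chans <- matrix(FALSE, nrow(a), 8)
    for (i in seq_len(nrow(a))) {
      chans[i, ] <- suppressWarnings(
        assign_channels(a$name[i], a$resname[i], a$element[i], is_metal[i])
      )
    }
    if (!include_metals) chans[is_metal, ] <- FALSE
    radii <- vdw_radius(a$element)
    for (c_ in 1:8) {
      sel <- chans[, c_]
      if (!any(sel)) next
      vals[, , , c_] <- .paint(vals[, , , c_], ax, xyz[sel, , drop = FALSE],
                               radii[sel])
    }
  }
  structure(list(values = vals, origin = origin, spacing = spacing,
                 channels = channel_names()),
            class = "voxel_grid")
}

#' Voxelize zinc sites into a binary target grid
#'
#' Paints the zinc ions with the same pair-correlation function (r_vdw(Zn)
#' = 1.39 A) on the frame of an existing grid, then binarizes at 0.05: any
#' voxel above 0.05 becomes 1 (true zinc location), all others 0.
#'
#' @param sites A `metal_sites` data frame (or an n x 3 matrix of
#'   positions).
#' @param frame A `voxel_grid` or `density_map` providing origin, spacing
#'   and spatial shape.
#' @param threshold Binarization threshold (default 0.05).
#' @return A `voxel_grid` with a single binary channel `"target"`.
#' @export
voxelize_target <- function(sites, frame, threshold = 0.05) {
  n <- dim(frame$values)[1:3]
  ax <- lapply(1:3, function(k) frame$origin[k] + (seq_len(n[k]) - 1) * frame$spacing)
  vals <- array(0, dim = n)
  xyz <- if (is.matrix(sites)) sites else cbind(sites$x, sites$y, sites$z)
  if (nrow(xyz)) {
    vals <- .paint(vals, ax, xyz, rep(vdw_radius("ZN"), nrow(xyz)))
  }
  vals <- array(as.numeric(vals > threshold), dim = n)
  structure(list(values = array(vals, dim = c(n, 1)), origin = frame$origin,
                 spacing = frame$spacing, channels = "target"),
            class = "voxel_grid")
}

#' Sample a balanced set of training residues
#'
#' Positives are residues whose C-alpha lies within 12 A of any zinc;
#' negatives are an equal-sized seeded random sample of the remaining
#' residues (all of them if fewer).
#'
#' @param structure A `pdb_structure`.
#' @param zinc_sites A `metal_sites` data frame.
#' @param seed Integer seed for the negative sampling.
#' @param radius Positive-class distance cutoff (default 12 A).
#' @return Data frame with `key` and `label` (`"positive"`/`"negative"`).
#' @export
sample_training_residues <- function(structure, zinc_sites, seed = 1,
                                     radius = 12) {
  a <- structure$atoms
  ca <- a[!a$het & a$name == "CA", , drop = FALSE]
  if (!nrow(ca)) {
    return(data.frame(key = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- residue_key(ca$chain, ca$resseq, ca$icode)
  if (nrow(zinc_sites)) {
    zx <- cbind(zinc_sites$x, zinc_sites$y, zinc_sites$z)
    dmin <- vapply(seq_len(nrow(ca)), function(i) {
      min(sqrt((zx[, 1] - ca$x[i])^2 + (zx[, 2] - ca$y[i])^2 +
                 (zx[, 3] - ca$z[i])^2))
    }, numeric(1))
    pos <- keys[dmin <= radius]
    rest <- keys[dmin > radius]
  } else {
    pos <- character(0)
    rest <- keys
  }
  if (!length(pos)) {
    return(data.frame(key = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  neg <- .with_seed(seed, {
    if (length(rest) <= length(pos)) rest else sample(rest, length(pos))
  })
  data.frame(key = c(pos, neg),
             label = rep(c("positive", "negative"), c(length(pos), length(neg))),
             stringsAsFactors = FALSE)
}
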