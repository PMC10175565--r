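# Synthetic metalloprotein generator: zinc sites with ideal polyhedral
# coordination, decoy residues, LINK records, and analytic density fields.
# Templates carry heavy atoms with idealized internal geometry only -- the
# algorithms under test consume geometry, not stereochemistry.

# Residue templates in a local frame: the primary donor atom at the origin,
# the metal direction along +z (metal at (0, 0, bond_length)). Other heavy
# atoms extend away from the metal with plausible bond lengths and angles.
.residue_templates <- local({
  bb <- function(anchor) {
    # generic backbone hung off a side-chain anchor point
    ca <- anchor + c(0.60, 1.10, -0.80)
    rbind(CA = ca, N = ca + c(-0.70, 1.20, -0.40), C = ca + c(1.30, 0.60, -0.50),
          O = ca + c(1.90, 1.55, -0.90))
  }
  tpl <- list()

  cb <- c(1.71, 0, -0.60)                      # generic donor->CB direction
  tpl$CYS <- rbind(SG = c(0, 0, 0), CB = cb, bb(cb))
  tpl$SER <- rbind(OG = c(0, 0, 0), CB = cb * 0.83, bb(cb * 0.83))
  thr_cb <- cb * 0.83
  tpl$THR <- rbind(OG1 = c(0, 0, 0), CB = thr_cb,
                   CG2 = thr_cb + c(0.40, 1.35, -0.55), bb(thr_cb))
  tpl$MET <- rbind(SD = c(0, 0, 0), CG = c(1.71, 0, -0.55),
                   CE = c(-1.39, 0.90, -0.72),
                   CB = c(1.71, 0, -0.55) + c(0.75, 0.85, -1.05),
                   bb(c(2.46, 0.85, -1.60)))
  lys_ce <- c(1.40, 0, -0.50)
  tpl$LYS <- rbind(NZ = c(0, 0, 0), CE = lys_ce,
                   CD = lys_ce + c(0.45, 1.20, -0.80),
                   CG = lys_ce + c(0.90, 2.40, -1.60),
                   CB = lys_ce + c(1.35, 3.60, -2.40),
                   bb(lys_ce + c(1.35, 3.60, -2.40)))

  # imidazole ring in the xz-plane, NE2 donor, lone pair along +z
  his_ring <- rbind(NE2 = c(0, 0, 0), CE1 = c(1.076, 0, -0.782),
                    ND1 = c(0.672, 0, -2.048), CG = c(-0.655, 0, -2.062),
                    CD2 = c(-1.108, 0, -0.805))
  his_cb <- c(-1.30, 0.95, -2.95)
  tpl$HIS <- rbind(his_ring, CB = his_cb, bb(his_cb))

  # carboxylate/amide heads: donor oxygen at origin, plane xz
  head3 <- function(nm) {
    m <- rbind(c(0, 0, 0), c(1.083, 0, -0.625), c(2.165, 0, 0.0))
    rownames(m) <- nm
    m
  }
  asp_cb <- c(1.84, 0.91, -1.57)
  glu_cg <- c(1.84, 0.91, -1.57)
  tpl$ASP <- rbind(head3(c("OD1", "CG", "OD2")), CB = asp_cb, bb(asp_cb))
  tpl$GLU <- rbind(head3(c("OE1", "CD", "OE2")), CG = glu_cg,
                   CB = glu_cg + c(0.55, 1.15, -0.75),
                   bb(glu_cg + c(0.55, 1.15, -0.75)))
  tpl$ASN <- rbind(head3(c("OD1", "CG", "ND2")), CB = asp_cb, bb(asp_cb))
  tpl$GLN <- rbind(head3(c("OE1", "CD", "NE2")), CG = glu_cg,
                   CB = glu_cg + c(0.55, 1.15, -0.75),
                   bb(glu_cg + c(0.55, 1.15, -0.75)))

  tyr_ring <- rbind(OH = c(0, 0, 0), CZ = c(0, 0, -1.38),
                    CE1 = c(1.20, 0, -2.07), CE2 = c(-1.20, 0, -2.07),
                    CD1 = c(1.20, 0, -3.46), CD2 = c(-1.20, 0, -3.46),
                    CG = c(0, 0, -4.15))
  tyr_cb <- c(0.45, 0.95, -5.25)
  tpl$TYR <- rbind(tyr_ring, CB = tyr_cb, bb(tyr_cb))

  # non-coordinating fillers used as decoys
  gly_ca <- c(0, 0, 0)
  tpl$GLY <- rbind(CA = gly_ca, N = gly_ca + c(-0.70, 1.20, -0.40),
                   C = gly_ca + c(1.30, 0.60, -0.50),
                   O = gly_ca + c(1.90, 1.55, -0.90))
  ala_cb <- c(0, 0, 0)
  tpl$ALA <- rbind(CB = ala_cb, bb(ala_cb))
  leu_cd <- c(0, 0, 0)
  tpl$LEU <- rbind(CD1 = leu_cd, CD2 = c(1.10, 1.05, 0.15),
                   CG = c(0.80, 0.35, -1.20), CB = c(1.45, 1.35, -2.10),
                   bb(c(1.45, 1.35, -2.10)))
  phe_ring <- rbind(CZ = c(0, 0, 0), CE1 = c(1.20, 0, -0.69),
                    CE2 = c(-1.20, 0, -0.69), CD1 = c(1.20, 0, -2.08),
                    CD2 = c(-1.20, 0, -2.08), CG = c(0, 0, -2.77))
  phe_cb <- c(0.45, 0.95, -3.90)
  tpl$PHE <- rbind(phe_ring, CB = phe_cb, bb(phe_cb))
  tpl
})

# letter -> residue name and primary donor placed at the polyhedral vertex
.letter_residue <- c(C = "CYS", H = "HIS", D = "ASP", E = "GLU", N = "ASN",
                     Q = "GLN", S = "SER", T = "THR", Y = "TYR", M = "MET",
                     K = "LYS")
.letter_donor <- c(C = "SG", H = "NE2", D = "OD1", E = "OE1", N = "OD1",
                   Q = "OE1", S = "OG", T = "OG1", Y = "OH", M = "SD",
                   K = "NZ")

.tetrahedral_vertices <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                               c(-1, -1, 1)) / sqrt(3)
.octahedral_vertices <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                              c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

# rotation taking unit vector `from` to unit vector `to` (Rodrigues)
.rotation_between <- function(from, to) {
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    perp <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

.rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * (vx %*% vx)
}

# uniform random rotation matrix (via quaternion)
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]), sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]), sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# place one residue: donor at `donor_pos`, donor->metal direction `to_metal`,
# random roll about that axis (consumes RNG)
.place_residue <- function(letter, donor_pos, to_metal) {
  resname <- .letter_residue[[letter]]
  tpl <- .residue_templates[[resname]]
  roll <- .rotation_about(c(0, 0, 1), stats::runif(1, 0, 2 * pi))
  rot <- .rotation_between(c(0, 0, 1), to_metal)
  coords <- t(rot %*% roll %*% t(tpl)) +
    matrix(donor_pos, nrow(tpl), 3, byrow = TRUE)
  data.frame(name = rownames(tpl), resname = resname,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             stringsAsFactors = FALSE)
}

#' Site specification for the synthetic generator
#'
#' @param motif Environment code, e.g. `"CCHH"`; one letter per coordinating
#'   residue. Supported letters: C,H,D,E,N,Q,S,T,Y,M,K.
#' @param geometry `"tetrahedral"` (4 donors, or 3 with the fourth vertex
#'   left vacant for implicit solvent) or `"octahedral"` (6 donors);
#'   inferred from the motif length when missing.
#' @param bond_length Metal-donor distance in Angstrom (default 2.2, the
#'   typical zinc coordination distance).
#' @param noise_sigma Isotropic Gaussian noise (per component, A) applied to
#'   each donor placement. Default 0.
#' @param center Site centre (metal position), xyz.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(motif, geometry = NULL, bond_length = 2.2,
                      noise_sigma = 0, center = c(0, 0, 0)) {
  motif <- toupper(motif)
  letters1 <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters1, names(.letter_residue))
  if (length(bad)) {
    stop("unsupported motif letter(s) ", paste(bad, collapse = ","),
         "; supported: ", paste(names(.letter_residue), collapse = ","),
         call. = FALSE)
  }
  if (is.null(geometry)) {
    geometry <- switch(as.character(length(letters1)),
                       "3" = "tetrahedral", "4" = "tetrahedral",
                       "6" = "octahedral",
                       stop("motif length must be 3, 4 or 6 unless geometry is given", call. = FALSE))
  }
  ncoord <- switch(geometry, tetrahedral = 4L, octahedral = 6L,
                   stop("geometry must be 'tetrahedral' or 'octahedral'", call. = FALSE))
  # a 3-letter tetrahedral motif occupies 3 vertices, leaving one vacant
  # (implicit solvent completes the shell)
  if (!(length(letters1) == ncoord ||
        (geometry == "tetrahedral" && length(letters1) == 3L))) {
    stop(sprintf("motif length %d does not match %s coordination number %d",
                 length(letters1), geometry, ncoord), call. = FALSE)
  }
  stopifnot(bond_length > 0, noise_sigma >= 0, length(center) == 3)
  structure(list(motif = motif, geometry = geometry, bond_length = bond_length,
                 noise_sigma = noise_sigma, center = as.numeric(center)),
            class = "site_spec")
}

#' Build one synthetic zinc site
#'
#' Places donor atoms at the ideal polyhedral vertices at `bond_length` from
#' the metal, perturbs each by isotropic Gaussian noise, builds full heavy-
#' atom residues oriented with the donor toward the metal, and emits one
#' LINK record per residue-metal contact carrying the realized distance.
#'
#' @param spec A [site_spec()].
#' @param seed Integer seed; the same seed reproduces coordinates exactly.
#' @param chain Chain identifier for the residues.
#' @param start_resseq First residue number to use.
#' @return A list with `atoms` (residue atoms, data frame), `site`
#'   (metal position/occupancy), and `links` (LINK table rows).
#' @export
make_zinc_site <- function(spec, seed = 1, chain = "A", start_resseq = 1L) {
  stopifnot(inherits(spec, "site_spec"))
  .with_seed(seed, {
    letters1 <- strsplit(spec$motif, "")[[1]]
    verts <- switch(spec$geometry, tetrahedral = .tetrahedral_vertices,
                    octahedral = .octahedral_vertices)
    atoms <- list(); links <- list()
    for (i in seq_along(letters1)) {
      u <- verts[i, ]
      donor_pos <- spec$center + spec$bond_length * u +
        stats::rnorm(3, 0, spec$noise_sigma)
      to_metal <- spec$center - donor_pos
      dist_real <- sqrt(sum(to_metal^2))
      to_metal <- to_metal / dist_real
      res <- .place_residue(letters1[i], donor_pos, to_metal)
      res$chain <- chain
      res$resseq <- start_resseq + i - 1L
      atoms[[i]] <- res
      links[[i]] <- data.frame(
        name1 = .letter_donor[[letters1[i]]], resname1 = res$resname[1],
        chain1 = chain, resseq1 = res$resseq[1], icode1 = "",
        name2 = "ZN", resname2 = "ZN", chain2 = chain, resseq2 = NA_integer_,
        icode2 = "", distance = round(dist_real, 2), stringsAsFactors = FALSE
      )
    }
    list(
      atoms = do.call(rbind, atoms),
      site = list(position = spec$center, occupancy = 1.0),
      links = do.call(rbind, links)
    )
  })
}

#' Generate a synthetic metalloprotein
#'
#' Realizes each site specification at a well-separated location inside a
#' cubic box, scatters decoy residues (a mix of coordinating and
#' non-coordinating types) with no heavy atom within `decoy_exclusion` of
#' any planted metal, and assembles a `pdb_structure` with complete LINK
#' records plus the planted ground truth.
#'
#' @param specs A list of [site_spec()] objects (centres are overridden by
#'   placement), or a character vector of motifs.
#' @param n_decoys Number of decoy residues to scatter.
#' @param box Cube edge length in Angstrom (default 40).
#' @param seed Integer seed; reproduces the structure exactly.
#' @param min_separation Minimum distance between planted metals (default
#'   20 A, keeping neighbouring coordination shells unambiguous).
#' @param decoy_exclusion No decoy heavy atom closer than this to a metal
#'   (default 6 A).
#' @param id Structure identifier.
#' @return A list of class `synth_protein`: `structure` (`pdb_structure`),
#'   `planted_sites` (`metal_sites` data frame), `site_specs`, `seed`.
#' @export
make_protein <- function(specs, n_decoys = 20, box = 40, seed = 1,
                         min_separation = 20, decoy_exclusion = 6,
                         id = sprintf("synth%04d", seed %% 10000)) {
  if (is.character(specs)) specs <- lapply(specs, site_spec)
  if (inherits(specs, "site_spec")) specs <- list(specs)
  stopifnot(min_separation >= 10)
  .with_seed(seed, {
    margin <- 8
    centers <- matrix(NA_real_, length(specs), 3)
    for (i in seq_along(specs)) {
      ok <- FALSE
      for (try in seq_len(500)) {
        cand <- stats::runif(3, margin, box - margin)
        if (i == 1 || all(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                                          matrix(cand, i - 1, 3, byrow = TRUE))^2)) >= min_separation)) {
          centers[i, ] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("box too small to separate ", length(specs),
                    " sites by ", min_separation, " A", call. = FALSE)
    }

    atoms <- list(); links <- list(); metals <- list()
    resseq <- 0L
    site_seeds <- sample.int(.Machine$integer.max, length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      sp$center <- centers[i, ]
      zs <- make_zinc_site(sp, seed = site_seeds[i], chain = "A",
                           start_resseq = resseq + 1L)
      resseq <- max(zs$atoms$resseq)
      atoms[[length(atoms) + 1L]] <- zs$atoms
      links[[length(links) + 1L]] <- zs$links
      metals[[i]] <- centers[i, ]
    }

    # decoys: mixed residue alphabet, no heavy atom near a planted metal
    decoy_pool <- c("GLY", "ALA", "LEU", "PHE", "SER", "HIS", "ASP", "CYS", "LYS")
    met_mat <- do.call(rbind, metals)
    n_placed <- 0L
    attempts <- 0L
    while (n_placed < n_decoys && attempts < n_decoys * 200L) {
      attempts <- attempts + 1L
      resname <- sample(decoy_pool, 1)
      tpl <- .residue_templates[[resname]]
      pos <- stats::runif(3, 2, box - 2)
      rot <- random_rotation()
      coords <- t(rot %*% t(tpl)) + matrix(pos, nrow(tpl), 3, byrow = TRUE)
      dmin <- min(sqrt(rowSums((coords[rep(seq_len(nrow(coords)), each = nrow(met_mat)), , drop = FALSE] -
                                  met_mat[rep(seq_len(nrow(met_mat)), nrow(coords)), , drop = FALSE])^2)))
      if (dmin < decoy_exclusion) next
      n_placed <- n_placed + 1L
      resseq <- resseq + 1L
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = rownames(tpl), resname = resname, x = coords[, 1],
        y = coords[, 2], z = coords[, 3], chain = "A", resseq = resseq,
        stringsAsFactors = FALSE
      )
    }
    if (n_placed < n_decoys) {
      stop("could not place ", n_decoys, " decoys outside the exclusion zone",
           call. = FALSE)
    }

    prot <- do.call(rbind, atoms)
    prot_df <- data.frame(
      serial = seq_len(nrow(prot)), name = prot$name,
      element = infer_element(formatC(prot$name, width = 4)),
      resname = prot$resname, chain = prot$chain, resseq = prot$resseq,
      icode = "", x = prot$x, y = prot$y, z = prot$z, occ = 1.0, bfac = 0.0,
      altloc = "", het = FALSE, stringsAsFactors = FALSE
    )
    metal_df <- data.frame(
      serial = nrow(prot) + seq_along(metals), name = "ZN", element = "ZN",
      resname = "ZN", chain = "A",
      resseq = resseq + seq_along(metals), icode = "",
      x = met_mat[, 1], y = met_mat[, 2], z = met_mat[, 3],
      occ = 1.0, bfac = 0.0, altloc = "", het = TRUE, stringsAsFactors = FALSE
    )
    link_df <- do.call(rbind, links)
    # fill in the metal residue numbers per site
    k <- 0L
    for (i in seq_along(specs)) {
      ncoord <- nchar(specs[[i]]$motif)
      link_df$resseq2[k + seq_len(ncoord)] <- metal_df$resseq[i]
      k <- k + ncoord
    }
    struct <- structure(list(id = id, atoms = rbind(prot_df, metal_df),
                             links = link_df), class = "pdb_structure")
    planted <- data.frame(
      element = "ZN", x = met_mat[, 1], y = met_mat[, 2], z = met_mat[, 3],
      occupancy = 1.0, chain = "A", resseq = metal_df$resseq, icode = "",
      bfac = 0.0, stringsAsFactors = FALSE
    )
    class(planted) <- c("metal_sites", "data.frame")
    structure(list(structure = struct, planted_sites = planted,
                   site_specs = specs, seed = seed),
              class = "synth_protein")
  })
}

#' Analytic Gaussian density field
#'
#' Each voxel takes the maximum over peaks of
#' `peak * exp(-||x - c||^2 / (2 sigma^2))`; a plain fixture for testing
#' density post-processing.
#'
#' @param peaks A list of lists with `center` (xyz), `height` in (0, 1],
#'   and `sigma` (A).
#' @param origin Centre of the corner voxel.
#' @param n Voxel count per axis (scalar or length-3).
#' @param spacing Voxel spacing in Angstrom (default 0.5).
#' @return A `density_map`.
#' @export
make_density <- function(peaks, origin = c(0, 0, 0), n = 32, spacing = 0.5) {
  if (length(n) == 1) n <- rep(n, 3)
  vals <- array(0, dim = n)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(n[k]) - 1) * spacing)
  for (pk in peaks) {
    stopifnot(pk$height > 0, pk$height <= 1, pk$sigma > 0)
    dx2 <- (ax[[1]] - pk$center[1])^2
    dy2 <- (ax[[2]] - pk$center[2])^2
    dz2 <- (ax[[3]] - pk$center[3])^2
    g <- pk$height * exp(-(outer(outer(dx2, dy2, "+"), dz2, "+")) / (2 * pk$sigma^2))
    vals <- pmax(vals, g)
  }
  structure(list(values = vals, counts = array(1L, dim = n),
                 origin = as.numeric(origin), spacing = spacing),
            class = "density_map")
}
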