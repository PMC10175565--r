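# Geometric metal-location prediction from the coordination-environment
# probability map: per-residue scoring, clustering, score-weighted placement
# and final site rescoring.

# Donor atoms defining the reference point of each coordinating residue type.
# Multi-donor residues use the donor midpoint, and their search radius is
# enlarged by the midpoint-to-donor distance.
.reference_donors <- list(
  CYS = "SG", HIS = c("ND1", "NE2"), ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1", SER = "OG",
  THR = "OG1", TYR = "OH", MET = "SD", LYS = "NZ"
)

#' Configuration for geometric site prediction
#'
#' @param search_radius Residue-scoring search radius in Angstrom; default
#'   5.5 (about 2.5x the typical 2.2 A metal-donor distance).
#' @param threshold_t Relative score threshold `t` in (0, 1]; residues (and
#'   final sites) scoring below `t` times the maximum are discarded.
#'   Default 0.5.
#' @param site_radius_fraction Fraction of the search radius used when
#'   rescoring a placed site (default 0.6, i.e. 3.3 A).
#' @param cluster_distance Distance below which high-scoring residues are
#'   grouped into one putative site; default twice the search radius.
#' @return A list of class `metal1d_config`.
#' @export
metal1d_config <- function(search_radius = 5.5, threshold_t = 0.5,
                           site_radius_fraction = 0.6,
                           cluster_distance = 2 * search_radius) {
  stopifnot(search_radius > 0, threshold_t > 0, threshold_t <= 1,
            site_radius_fraction > 0, site_radius_fraction <= 1,
            cluster_distance > 0)
  structure(list(search_radius = search_radius, threshold_t = threshold_t,
                 site_radius_fraction = site_radius_fraction,
                 cluster_distance = cluster_distance),
            class = "metal1d_config")
}

#' Reference point of a coordinating residue
#'
#' Single-donor residues return the donor atom position with a zero radius
#' increment; multi-donor residues (His, Asp, Glu) return the midpoint of
#' the two donors and an increment equal to the midpoint-donor distance,
#' so the search radius can be enlarged accordingly.
#'
#' @param residue A data frame of the residue's atoms (rows of a
#'   `pdb_structure` atom table).
#' @return A list with `position` (xyz), `increment` (A), `letter`,
#'   and `key`.
#' @export
reference_point <- function(residue) {
  resname <- residue$resname[1]
  donors <- .reference_donors[[resname]]
  if (is.null(donors)) {
    stop(structure(class = c("metalloc_missing_atom", "error", "condition"),
                   list(message = sprintf("residue %s has no coordinating side chain", resname),
                        call = NULL)))
  }
  idx <- match(donors, residue$name)
  if (anyNA(idx)) {
    stop(structure(class = c("metalloc_missing_atom", "error", "condition"),
                   list(message = sprintf("residue %s is missing donor atom(s) %s",
                                          resname, paste(donors[is.na(idx)], collapse = ",")),
                        call = NULL)))
  }
  pos <- cbind(residue$x[idx], residue$y[idx], residue$z[idx])
  mid <- colMeans(pos)
  inc <- if (length(donors) > 1) sqrt(sum((pos[1, ] - mid)^2)) else 0
  list(position = as.numeric(mid), increment = inc,
       letter = unname(.aa3to1[resname]),
       key = residue_key(residue$chain[1], residue$resseq[1], residue$icode[1]))
}

# Table of reference points for all supported residues of a structure.
# Residues of unsupported types are skipped silently; supported residues
# missing their donor atoms are skipped with a warning.
residue_reference_points <- function(structure) {
  res <- split_residues(structure)
  rows <- list()
  for (r in res) {
    if (!(r$resname[1] %in% names(.reference_donors))) next
    rp <- tryCatch(reference_point(r), metalloc_missing_atom = function(e) {
      warning(conditionMessage(e), call. = FALSE); NULL
    })
    if (is.null(rp)) next
    rows[[length(rows) + 1L]] <- data.frame(
      key = rp$key, letter = rp$letter,
      x = rp$position[1], y = rp$position[2], z = rp$position[3],
      increment = rp$increment, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(key = character(), letter = character(), x = numeric(),
                      y = numeric(), z = numeric(), increment = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compatibility score of an observed neighbourhood
#'
#' Sums the probabilities of all map environments that are sub-multisets of
#' the observed letter multiset. A score of 1 corresponds to a neighbourhood
#' compatible with every environment in the map (the ideal, fully
#' surrounded case); in practice scores fall in [0, 1).
#'
#' @param observed Character vector of observed 1-letter codes (a multiset).
#' @param map A `probability_map`.
#' @return Numeric score in [0, 1].
#' @export
compatibility_score <- function(observed, map) {
  stopifnot(inherits(map, "probability_map"), nrow(map) >= 1)
  if (!length(observed)) return(0)
  obs_tab <- table(toupper(observed))
  total <- 0
  for (i in seq_len(nrow(map))) {
    env <- strsplit(map$environment[i], "")[[1]]
    env_tab <- table(env)
    ok <- all(names(env_tab) %in% names(obs_tab)) &&
      all(env_tab <= obs_tab[names(env_tab)])
    if (ok) total <- total + map$probability[i]
  }
  total
}

#' Score every supported residue of a structure
#'
#' Performs a geometric search from each residue's reference point: the
#' observed multiset is the residue's own letter plus the letters of all
#' other reference points within `search_radius + increment`, and the score
#' is the map compatibility of that multiset.
#'
#' @param structure A `pdb_structure`.
#' @param map A `probability_map`.
#' @param config A `metal1d_config`.
#' @return A data frame of class `residue_scores`: `key`, `letter`, `x`,
#'   `y`, `z`, `increment`, `score`.
#' @export
score_residues <- function(structure, map, config = metal1d_config()) {
  rp <- residue_reference_points(structure)
  if (!nrow(rp)) {
    warning("no supported coordinating residues in structure", call. = FALSE)
    rp$score <- numeric(0)
    class(rp) <- c("residue_scores", "data.frame")
    return(rp)
  }
  xyz <- as.matrix(rp[, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  scores <- numeric(nrow(rp))
  for (i in seq_len(nrow(rp))) {
    radius <- config$search_radius + rp$increment[i]
    nb <- which(dmat[i, ] <= radius)
    nb <- setdiff(nb, i)
    observed <- c(rp$letter[i], rp$letter[nb])
    scores[i] <- compatibility_score(observed, map)
  }
  rp$score <- scores
  class(rp) <- c("residue_scores", "data.frame")
  rp
}

# connected components of an undirected adjacency matrix (logical)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cluster high-scoring residues and place putative sites
#'
#' Residues scoring at least `threshold_t` times the maximum residue score
#' are grouped into connected components under the "closer than
#' `cluster_distance`" relation; each cluster yields one putative site at
#' the score-weighted average of its members' reference points. An isolated
#' residue is paired with the nearest other reference point, which is
#' assigned a fictitious copy of its score, so the site falls at their
#' midpoint.
#'
#' @param scores A `residue_scores` data frame from [score_residues()].
#' @param config A `metal1d_config`.
#' @return A data frame of class `predicted_sites`: `x`, `y`, `z`, `score`
#'   (provisional: maximum member score) and a `members` list column of
#'   residue keys.
#' @export
cluster_and_place <- function(scores, config = metal1d_config()) {
  empty <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("predicted_sites", "data.frame")
  if (!nrow(scores) || max(scores$score) <= 0) return(empty)

  smax <- max(scores$score)
  high <- which(scores$score >= config$threshold_t * smax - 1e-12)
  hs <- scores[high, , drop = FALSE]
  xyz_all <- as.matrix(scores[, c("x", "y", "z")])
  xyz <- xyz_all[high, , drop = FALSE]
  dmat <- as.matrix(stats::dist(xyz))
  adj <- dmat < config$cluster_distance
  diag(adj) <- FALSE
  comp <- .components(adj)

  out <- list()
  for (cid in sort(unique(comp))) {
    mem <- which(comp == cid)
    pos <- xyz[mem, , drop = FALSE]
    w <- hs$score[mem]
    keys <- hs$key[mem]
    if (length(mem) == 1L && nrow(scores) > 1L) {
      # isolated high scorer: augment with the nearest other reference point
      # carrying a fictitious copy of the score -> midpoint placement
      self_idx <- high[mem]
      d <- sqrt(rowSums((xyz_all - matrix(xyz_all[self_idx, ], nrow(xyz_all), 3, byrow = TRUE))^2))
      d[self_idx] <- Inf
      cand <- which(d == min(d))
      nn <- cand[order(scores$key[cand])][1]   # ties: lowest residue key
      pos <- rbind(pos, xyz_all[nn, ])
      w <- c(w, w[1])
      keys <- c(keys, scores$key[nn])
    }
    site <- colSums(pos * w) / sum(w)
    out[[length(out) + 1L]] <- list(x = site[1], y = site[2], z = site[3],
                                    score = max(hs$score[mem]), members = keys)
  }
  sites <- data.frame(
    x = vapply(out, `[[`, numeric(1), "x"),
    y = vapply(out, `[[`, numeric(1), "y"),
    z = vapply(out, `[[`, numeric(1), "z"),
    score = vapply(out, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE
  )
  sites$members <- lapply(out, `[[`, "members")
  class(sites) <- c("predicted_sites", "data.frame")
  sites
}

#' Rescore placed sites and filter unlikely ones
#'
#' Each putative site receives a final score by a geometric search centred
#' on the site itself: the compatibility of the letters of all residues
#' whose reference points fall within `site_radius_fraction * search_radius`
#' (enlarged by each residue's increment) of the site. Sites with zero
#' score, or scoring below `threshold_t` times the best final score, are
#' removed; this resolves placement artifacts such as the fictitious-score
#' midpoints of isolated residues ending up in empty space.
#'
#' @param sites A `predicted_sites` data frame from [cluster_and_place()].
#' @param structure The `pdb_structure` the sites belong to.
#' @param map A `probability_map`.
#' @param config A `metal1d_config`.
#' @return A filtered `predicted_sites` data frame with final scores.
#' @export
score_sites <- function(sites, structure, map, config = metal1d_config()) {
  if (!nrow(sites)) return(sites)
  rp <- residue_reference_points(structure)
  base_radius <- config$site_radius_fraction * config$search_radius
  final <- numeric(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    d <- sqrt((rp$x - sites$x[i])^2 + (rp$y - sites$y[i])^2 + (rp$z - sites$z[i])^2)
    nb <- which(d <= base_radius + rp$increment)
    final[i] <- if (length(nb)) compatibility_score(rp$letter[nb], map) else 0
  }
  sites$score <- final
  keep <- final > 0 & final >= config$threshold_t * max(final) - 1e-12
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("predicted_sites", "data.frame")
  sites
}

#' Predict metal sites from geometry
#'
#' Full geometric pipeline: residue scoring against the probability map,
#' clustering and score-weighted placement, then site rescoring and
#' threshold filtering. Sites are returned sorted by final score
#' (descending), ties broken by position.
#'
#' @param structure A `pdb_structure`.
#' @param map A `probability_map`.
#' @param config A `metal1d_config`.
#' @return A `predicted_sites` data frame (`x`, `y`, `z`, `score`,
#'   `members`).
#' @export
predict_metal1d <- function(structure, map, config = metal1d_config()) {
  scores <- score_residues(structure, map, config)
  sites <- cluster_and_place(scores, config)
  sites <- score_sites(sites, structure, map, config)
  if (nrow(sites)) {
    ord <- order(-sites$score, sites$x, sites$y, sites$z)
    sites <- sites[ord, , drop = FALSE]
    rownames(sites) <- NULL
  }
  class(sites) <- c("predicted_sites", "data.frame")
  sites
}

#' Write predicted sites as a PDB file
#'
#' Sites become HETATM ZN records with the score in the B-factor column.
#'
#' @param sites A `predicted_sites` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_pdb <- function(sites, path) {
  n <- nrow(sites)
  lines <- character(0)
  if (n) {
    lines <- sprintf(
      "HETATM%5d ZN    ZN Z%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          ZN",
      seq_len(n), seq_len(n), sites$x, sites$y, sites$z, 1.0,
      pmin(sites$score, 999.99)
    )
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a predicted-site report as TSV
#'
#' Columns: rank, x, y, z, score, member_residues (comma separated).
#'
#' @param sites A `predicted_sites` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  members <- if (!is.null(sites$members)) {
    vapply(sites$members, paste, character(1), collapse = ",")
  } else rep("", nrow(sites))
  df <- data.frame(rank = seq_len(nrow(sites)), x = sites$x, y = sites$y,
                   z = sites$z, score = sites$score,
                   member_residues = members, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
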