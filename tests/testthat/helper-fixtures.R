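# Shared fixtures: tiny hand-written PDB texts and small synthetic corpora.

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          occ = 1.0, altloc = " ", element = NULL, het = FALSE,
                          icode = " ") {
  if (is.null(element)) element <- metalloc::infer_element(formatC(name, width = 4))
  nm <- if (nchar(element) >= 2 || nchar(name) >= 4) {
    formatC(name, width = -4)
  } else {
    formatC(paste0(" ", name), width = -4)
  }
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, nm, altloc, resname, chain,
          resseq, icode, x, y, z, occ, 0, element)
}

pdb_link_line <- function(name1, resname1, chain1, resseq1,
                          name2, resname2, chain2, resseq2, dist = NA) {
  sprintf("LINK        %-4s %3s %1s%4d                %-4s %3s %1s%4d   1555   1555 %5s",
          name1, resname1, chain1, resseq1, name2, resname2, chain2, resseq2,
          if (is.na(dist)) "     " else sprintf("%5.2f", dist))
}

write_pdb_text <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# a reference map with known probabilities, built without LINK mining
toy_map <- function(probs) {
  map <- data.frame(environment = names(probs), count = 1L,
                    probability = unname(probs),
                    n_structures = 1L, stringsAsFactors = FALSE)
  attr(map, "total_count") <- length(probs)
  class(map) <- c("probability_map", "data.frame")
  map
}

# independent sub-multiset compatibility oracle: tries to injectively map
# the environment's letters into the observed letters by exhaustive greedy
# removal (multiset containment via repeated deletion)
oracle_compat <- function(observed, map) {
  total <- 0
  for (i in seq_len(nrow(map))) {
    env <- strsplit(map$environment[i], "")[[1]]
    pool <- observed
    ok <- TRUE
    for (ch in env) {
      j <- match(ch, pool)
      if (is.na(j)) { ok <- FALSE; break }
      pool <- pool[-j]
    }
    if (ok) total <- total + map$probability[i]
  }
  total
}

# naive average-linkage threshold clustering (quadratic, loop-based),
# independent of stats::hclust
oracle_avg_cluster <- function(xyz, threshold) {
  n <- nrow(xyz)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(as.matrix(stats::dist(rbind(xyz[clusters[[i]], , drop = FALSE],
                                              xyz[clusters[[j]], , drop = FALSE]))
        )[seq_along(clusters[[i]]),
          length(clusters[[i]]) + seq_along(clusters[[j]]), drop = FALSE])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    if (bestd > threshold) break
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  cl <- integer(n)
  for (i in seq_along(clusters)) cl[clusters[[i]]] <- i
  cl
}

# brute-force evaluation of the matching rules, independent of the
# implementation in match_predictions
oracle_match <- function(pred, truth, radius = 5) {
  np <- nrow(pred); nt <- nrow(truth)
  tp <- 0L; fn <- 0L
  matched <- logical(np)
  for (j in seq_len(nt)) {
    hit <- FALSE
    for (i in seq_len(np)) {
      if (sqrt(sum((pred[i, ] - truth[j, ])^2)) <= radius) {
        hit <- TRUE
        matched[i] <- TRUE
      }
    }
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  rest <- pred[!matched, , drop = FALSE]
  fp <- if (nrow(rest)) length(unique(oracle_avg_cluster(rest, radius))) else 0L
  list(tp = tp, fp = fp, fn = fn)
}

random_rigid_transform <- function() {
  rot <- metalloc:::random_rotation()
  shift <- stats::runif(3, -20, 20)
  list(rot = rot, shift = shift,
       apply = function(xyz) t(rot %*% t(xyz)) + matrix(shift, nrow(xyz), 3, byrow = TRUE))
}

transform_structure <- function(st, tf) {
  xyz <- tf$apply(cbind(st$atoms$x, st$atoms$y, st$atoms$z))
  st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
  st
}
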