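# Coordination-environment mining from LINK records and the probability map
# that drives geometric site scoring.

#' Canonicalize a coordination environment code
#'
#' Sorts the 1-letter codes ascending so that, e.g., "CHC" and "CCH" denote
#' the same environment.
#'
#' @param code Character vector of environment codes (e.g. `"CHC"`).
#' @return Canonical (sorted) codes.
#' @export
canonical_environment <- function(code) {
  vapply(strsplit(toupper(code), ""), function(s) paste(sort(s), collapse = ""),
         character(1))
}

# Resolve the amino-acid partners of each metal ion of `element` via LINK
# records. Returns one row per retained metal--amino-acid link:
#   metal_key, partner_key, letter, donor atom name, distance (from coords).
# Retention rules: water partners dropped; unresolvable partners skipped with
# a warning; metals with < 2 *distinct* amino-acid partners contribute
# nothing (weak/artifact sites).
metal_link_table <- function(structure, element = "ZN") {
  stopifnot(inherits(structure, "pdb_structure"))
  lk <- structure$links
  a <- structure$atoms
  empty <- data.frame(metal_key = character(), partner_key = character(),
                      letter = character(), donor = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (is.null(lk) || !nrow(lk)) return(empty)

  rows <- list()
  for (i in seq_len(nrow(lk))) {
    r <- lk[i, ]
    sides <- list(
      list(name = r$name1, resname = r$resname1, chain = r$chain1,
           resseq = r$resseq1, icode = r$icode1),
      list(name = r$name2, resname = r$resname2, chain = r$chain2,
           resseq = r$resseq2, icode = r$icode2)
    )
    is_metal <- vapply(sides, function(s) identical(toupper(s$resname), toupper(element)), logical(1))
    if (sum(is_metal) != 1) next          # metal-metal or no-metal link: not an environment link
    metal <- sides[[which(is_metal)]]
    partner <- sides[[which(!is_metal)]]
    if (partner$resname %in% .water_names) next

    letter <- unname(.aa3to1[partner$resname])
    if (is.na(letter)) {
      parent <- unname(.modified_parent[partner$resname])
      if (!is.na(parent) && !is.null(parent)) {
        letter <- unname(.aa3to1[parent])
      } else {
        warning(sprintf("LINK partner %s %s%s not a standard amino acid; skipped",
                        partner$resname, partner$chain, partner$resseq), call. = FALSE)
        next
      }
    }

    msel <- a$het & toupper(a$resname) == toupper(element) &
      a$chain == metal$chain & a$resseq == metal$resseq &
      trimws(a$icode) == trimws(metal$icode)
    psel <- a$chain == partner$chain & a$resseq == partner$resseq &
      trimws(a$icode) == trimws(partner$icode) & a$name == partner$name
    if (!any(msel) || !any(psel)) {
      warning(sprintf("LINK record %d: partner not resolvable in structure '%s'; skipped",
                      i, structure$id), call. = FALSE)
      next
    }
    mi <- which(msel)[1]; pj <- which(psel)[1]
    d <- sqrt((a$x[mi] - a$x[pj])^2 + (a$y[mi] - a$y[pj])^2 + (a$z[mi] - a$z[pj])^2)
    rows[[length(rows) + 1L]] <- data.frame(
      metal_key = residue_key(a$chain[mi], a$resseq[mi], a$icode[mi]),
      partner_key = residue_key(a$chain[pj], a$resseq[pj], a$icode[pj]),
      letter = letter, donor = partner$name, distance = d,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)

  # drop metals with < 2 distinct amino-acid partners
  n_per_metal <- tapply(tab$partner_key, tab$metal_key, function(k) length(unique(k)))
  keep <- tab$metal_key %in% names(n_per_metal)[n_per_metal >= 2]
  tab[keep, , drop = FALSE]
}

#' Extract coordination environments from LINK records
#'
#' For each metal ion of `element`, the distinct amino-acid residues linked
#' to it each contribute one 1-letter code; the codes are sorted into a
#' canonical environment string. Links to water are dropped, and metals left
#' with fewer than two distinct amino-acid partners emit nothing.
#'
#' @param structure A `pdb_structure` parsed with LINK records.
#' @param element Metal component code (default `"ZN"`).
#' @return Character vector of canonical environment codes, one per
#'   retained metal ion.
#' @export
extract_environments <- function(structure, element = "ZN") {
  tab <- metal_link_table(structure, element)
  if (!nrow(tab)) return(character(0))
  keys <- unique(tab$metal_key)   # stable: first appearance in the link table
  vapply(keys, function(k) {
    sub <- tab[tab$metal_key == k, , drop = FALSE]
    letters1 <- vapply(split(sub$letter, sub$partner_key), `[`, character(1), 1)
    paste(sort(unname(letters1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a coordination-environment probability map
#'
#' Aggregates environment counts over a corpus and normalizes by the total
#' count, so each entry's probability is its relative frequency among all
#' observed environments.
#'
#' @param structures A list of `pdb_structure` objects.
#' @param element Metal component code (default `"ZN"`).
#' @return A data frame of class `probability_map` with columns
#'   `environment`, `count`, `probability`, `n_structures`, plus attributes
#'   `total_count` and `source_ids`.
#' @export
build_probability_map <- function(structures, element = "ZN") {
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  env_list <- lapply(structures, extract_environments, element = element)
  ids <- vapply(structures, function(s) s$id, character(1))
  all_envs <- unlist(env_list, use.names = FALSE)
  if (!length(all_envs)) {
    stop("no coordination environments found in the corpus; cannot build a probability map",
         call. = FALSE)
  }
  counts <- table(all_envs)
  # distinct source structures per environment
  per_struct <- mapply(function(envs, id) unique(envs), env_list, ids, SIMPLIFY = FALSE)
  nstruct <- vapply(names(counts), function(e) {
    sum(vapply(per_struct, function(u) e %in% u, logical(1)))
  }, integer(1))
  total <- sum(counts)
  map <- data.frame(
    environment = names(counts),
    count = as.integer(counts),
    probability = as.numeric(counts) / total,
    n_structures = as.integer(nstruct),
    stringsAsFactors = FALSE
  )
  map <- map[order(-map$count, map$environment), , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "total_count") <- as.integer(total)
  attr(map, "source_ids") <- ids
  class(map) <- c("probability_map", "data.frame")
  map
}

#' Metal--donor distance statistics from LINK records
#'
#' Mean and population standard deviation of the metal-to-donor-atom
#' distances, computed from the coordinates (not the optional LINK distance
#' column), over the same links retained by [extract_environments()].
#'
#' @param structures A list of `pdb_structure` objects (or one).
#' @param element Metal component code (default `"ZN"`).
#' @return A list with `mean`, `std` (population), and `n`.
#' @export
link_distance_stats <- function(structures, element = "ZN") {
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  d <- unlist(lapply(structures, function(s) metal_link_table(s, element)$distance))
  if (!length(d)) stop("no retained metal-amino-acid links; distance statistics undefined",
                       call. = FALSE)
  m <- mean(d)
  list(mean = m, std = sqrt(mean((d - m)^2)), n = length(d))
}

#' Write a probability map as TSV
#'
#' Columns: `environment`, `count`, `probability`, `n_structures`. A JSON
#' sidecar (`<path>.json`) records the total count and source structure ids.
#'
#' @param map A `probability_map`.
#' @param path Output TSV path.
#' @param sidecar Write the provenance sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(map, path, sidecar = TRUE) {
  stopifnot(inherits(map, "probability_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(total_count = attr(map, "total_count"),
           source_ids = attr(map, "source_ids")),
      paste0(path, ".json"), auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Read a probability map from TSV
#'
#' @param path TSV path written by [write_probability_map()].
#' @return A `probability_map`.
#' @export
read_probability_map <- function(path) {
  map <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, colClasses = c(environment = "character"))
  stopifnot(all(c("environment", "count", "probability", "n_structures") %in% names(map)))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(map, "total_count") <- meta$total_count
    attr(map, "source_ids") <- meta$source_ids
  } else {
    attr(map, "total_count") <- sum(map$count)
  }
  class(map) <- c("probability_map", "data.frame")
  map
}
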