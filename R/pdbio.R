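# PDB reading/writing and metal-site utilities.
#
# The parser is deliberately narrow: fixed-column ATOM/HETATM/LINK/MODEL
# records, one model, altLoc resolution by occupancy. mmCIF is not supported.

#' Standard amino-acid three-letter codes
#'
#' The twenty standard residues recognised as "protein" throughout the
#' package (ligand counting, environment extraction, voxel typing).
#'
#' @return Character vector of 3-letter codes.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

# water residue names, PDB convention
.water_names <- c("HOH", "WAT", "DOD")

# 3-letter -> 1-letter, standard residues
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# common modified residues mapped to their standard parent; anything else
# linked to a metal is skipped with a warning rather than silently dropped
.modified_parent <- c(
  MSE = "MET", CSO = "CYS", CSD = "CYS", OCS = "CYS", CME = "CYS",
  SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS", M3L = "LYS",
  HIC = "HIS", HSD = "HIS", HSE = "HIS"
)

residue_key <- function(chain, resseq, icode) {
  icode <- trimws(icode)
  paste0(chain, resseq, ifelse(icode == "", "", icode))
}

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element columns (77-78) are blank, per the v3.3 atom-name
#' justification convention: two-letter elements occupy columns 13-14, and
#' a leading digit marks a hydrogen variant.
#'
#' @param name Atom-name field exactly as read (4 characters, may be padded).
#' @return Element symbol, uppercase.
#' @export
infer_element <- function(name) {
  raw <- formatC(name, width = 4, flag = " ")
  vapply(raw, function(nm) {
    two <- substr(nm, 1, 2)
    if (grepl("^[0-9]", trimws(nm))) return("H")
    two_clean <- gsub("[^A-Za-z]", "", two)
    if (substr(nm, 1, 1) != " " && nchar(two_clean) == 2) {
      return(toupper(two_clean))
    }
    first <- gsub("[^A-Za-z]", "", trimws(nm))
    toupper(substr(first, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

.parse_coord <- function(txt, lineno, what) {
  val <- suppressWarnings(as.numeric(txt))
  bad <- is.na(val) & !grepl("^\\s*$", txt) | is.na(val)
  if (any(bad)) {
    stop(sprintf("unparseable %s field at line %d: '%s'",
                 what, lineno[which(bad)[1]], txt[which(bad)[1]]),
         call. = FALSE)
  }
  val
}

#' Read a protein structure from a PDB file
#'
#' Applies the model and conformer conventions used throughout the package:
#' only the first MODEL is retained; where altLoc duplicates exist only the
#' highest-occupancy conformer is kept (ties broken by altLoc identifier,
#' ascending); hydrogens are dropped; waters are dropped unless requested.
#' LINK records are parsed verbatim into a link table.
#'
#' @param path Path to a PDB-format file.
#' @param keep_water Keep water (HOH/WAT/DOD) atoms? Default `FALSE`.
#' @param id Structure identifier; defaults to the file base name.
#' @return An object of class `pdb_structure`: a list with `id`, an `atoms`
#'   data frame (serial, name, element, resname, chain, resseq, icode,
#'   x, y, z, occ, bfac, altloc, het) and a `links` data frame.
#' @export
read_pdb <- function(path, keep_water = FALSE, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  rec <- substr(lines, 1, 6)

  # first model only
  model_idx <- which(trimws(rec) == "MODEL")
  if (length(model_idx) > 1) {
    endmdl <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endmdl)) endmdl[1] else model_idx[2]
    keep <- seq_along(lines) < model_idx[2] & seq_along(lines) <= stop_at
    # records before MODEL 1 (e.g. LINK) are kept too
    keep <- keep | seq_along(lines) < model_idx[1]
    lines <- lines[keep]
    rec <- rec[keep]
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  links <- parse_link_records(lines[rec == "LINK  " | substr(lines, 1, 4) == "LINK"])

  if (!length(atom_lines)) stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)

  f <- function(a, b) substr(atom_lines, a, b)
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(f(7, 11))),
    name    = trimws(f(13, 16)),
    element = trimws(f(77, 78)),
    resname = trimws(f(18, 20)),
    chain   = trimws(f(22, 22)),
    resseq  = suppressWarnings(as.integer(f(23, 26))),
    icode   = trimws(f(27, 27)),
    x = .parse_coord(f(31, 38), atom_lineno, "x coordinate"),
    y = .parse_coord(f(39, 46), atom_lineno, "y coordinate"),
    z = .parse_coord(f(47, 54), atom_lineno, "z coordinate"),
    occ  = suppressWarnings(as.numeric(f(55, 60))),
    bfac = suppressWarnings(as.numeric(f(61, 66))),
    altloc = trimws(f(17, 17)),
    het = substr(atom_lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1.0   # missing occupancy defaults to 1.0
  atoms$bfac[is.na(atoms$bfac)] <- 0.0
  blank_el <- atoms$element == ""
  if (any(blank_el)) atoms$element[blank_el] <- infer_element(substr(atom_lines[blank_el], 13, 16))
  atoms$element <- toupper(atoms$element)

  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (!keep_water) atoms <- atoms[!(atoms$resname %in% .water_names), , drop = FALSE]

  # altLoc resolution: per (chain, resseq, icode, resname, atom name) keep the
  # highest-occupancy conformer, ties by altLoc ascending
  akey <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname, atoms$name, sep = "\r")
  ord <- order(akey, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(akey[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$serial), , drop = FALSE]
  rownames(atoms) <- NULL

  if (!nrow(atoms)) stop("empty structure: no atoms left after filtering in ", path, call. = FALSE)

  structure(list(id = id, atoms = atoms, links = links), class = "pdb_structure")
}

parse_link_records <- function(lines) {
  if (!length(lines)) {
    return(data.frame(
      name1 = character(), resname1 = character(), chain1 = character(),
      resseq1 = integer(), icode1 = character(),
      name2 = character(), resname2 = character(), chain2 = character(),
      resseq2 = integer(), icode2 = character(),
      distance = numeric(), stringsAsFactors = FALSE
    ))
  }
  f <- function(a, b) trimws(substr(lines, a, b))
  data.frame(
    name1 = f(13, 16), resname1 = f(18, 20), chain1 = f(22, 22),
    resseq1 = suppressWarnings(as.integer(f(23, 26))), icode1 = f(27, 27),
    name2 = f(43, 46), resname2 = f(48, 50), chain2 = f(52, 52),
    resseq2 = suppressWarnings(as.integer(f(53, 56))), icode2 = f(57, 57),
    distance = suppressWarnings(as.numeric(f(74, 78))),
    stringsAsFactors = FALSE
  )
}

#' Write a structure to a PDB file
#'
#' Fixed-column PDB v3.3 layout, coordinates at 3-decimal precision.
#' LINK records are written before the coordinate section.
#'
#' @param structure A `pdb_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  out <- character(0)
  lk <- structure$links
  if (!is.null(lk) && nrow(lk)) {
    out <- c(out, sprintf(
      "LINK        %-4s %3s %1s%4d%1s               %-4s %3s %1s%4d%1s  1555   1555 %5s",
      substr(lk$name1, 1, 4), lk$resname1, lk$chain1, lk$resseq1,
      ifelse(lk$icode1 == "", " ", lk$icode1),
      substr(lk$name2, 1, 4), lk$resname2, lk$chain2, lk$resseq2,
      ifelse(lk$icode2 == "", " ", lk$icode2),
      ifelse(is.na(lk$distance), "     ", sprintf("%5.2f", lk$distance))
    ))
  }
  pad_name <- function(nm, el) {
    # one-letter elements start in column 14, two-letter in column 13
    ifelse(nchar(el) >= 2 | nchar(nm) >= 4, formatC(nm, width = -4),
           formatC(paste0(" ", nm), width = -4))
  }
  out <- c(out, sprintf(
    "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$het, "HETATM", "ATOM"), a$serial %% 100000,
    pad_name(a$name, a$element),
    ifelse(a$altloc == "", " ", a$altloc), a$resname, a$chain, a$resseq,
    ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, a$occ, a$bfac, a$element
  ), "END")
  writeLines(out, path)
  invisible(path)
}

#' Extract metal sites from a structure
#'
#' One site per matching HETATM, in file order; used both for ground-truth
#' extraction during evaluation and to pull predicted sites back out of a
#' written prediction file.
#'
#' @param structure A `pdb_structure`.
#' @param element Chemical component code of the metal (default `"ZN"`).
#' @return A data frame of class `metal_sites` with columns `element`, `x`,
#'   `y`, `z`, `occupancy`, `chain`, `resseq`, `icode`, `bfac`.
#' @export
extract_metal_sites <- function(structure, element = "ZN") {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  sel <- a$het & a$resname == toupper(element)
  s <- data.frame(
    element = a$resname[sel], x = a$x[sel], y = a$y[sel], z = a$z[sel],
    occupancy = a$occ[sel], chain = a$chain[sel], resseq = a$resseq[sel],
    icode = a$icode[sel], bfac = a$bfac[sel], stringsAsFactors = FALSE
  )
  class(s) <- c("metal_sites", "data.frame")
  s
}

.site_xyz <- function(site) {
  if (is.numeric(site) && length(site) == 3) return(as.numeric(site))
  as.numeric(c(site$x[1], site$y[1], site$z[1]))
}

#' Count unique protein ligands around a metal site
#'
#' Number of distinct standard amino-acid residues with at least one heavy
#' atom (side chain or backbone) within `radius` of the site. Waters, hetero
#' ligands and modified residues do not count.
#'
#' @param site A `metal_sites` row, or a numeric xyz vector.
#' @param structure A `pdb_structure`.
#' @param radius Search radius in Angstrom (default 2.8).
#' @return Integer count of distinct coordinating residues.
#' @export
count_unique_protein_ligands <- function(site, structure, radius = 2.8) {
  stopifnot(radius > 0)
  p <- .site_xyz(site)
  a <- structure$atoms
  prot <- !a$het & a$resname %in% standard_residues()
  if (!any(prot)) return(0L)
  a <- a[prot, , drop = FALSE]
  d2 <- (a$x - p[1])^2 + (a$y - p[2])^2 + (a$z - p[3])^2
  hit <- d2 <= radius^2
  length(unique(residue_key(a$chain[hit], a$resseq[hit], a$icode[hit])))
}

#' Classify the quality of an experimental metal site
#'
#' Labels follow the artifact filters used in benchmark curation:
#' `artifact_like` if the site has fewer than 2 unique protein ligands within
#' 2.8 A or occupancy <= 0.5; `preorganized_3plus` if it has at least 3
#' unique protein ligands and occupancy > 0.5; otherwise `coordinated_2plus`.
#'
#' @param site A `metal_sites` row (occupancy is read from it) or an xyz
#'   vector together with `occupancy`.
#' @param structure A `pdb_structure`.
#' @param radius Ligand search radius in Angstrom (default 2.8).
#' @param occupancy Occupancy override when `site` is a bare xyz vector.
#' @return One of `"artifact_like"`, `"coordinated_2plus"`,
#'   `"preorganized_3plus"`.
#' @export
classify_site_quality <- function(site, structure, radius = 2.8, occupancy = NULL) {
  occ <- if (!is.null(occupancy)) occupancy
         else if (!is.null(site$occupancy)) site$occupancy[1]
         else 1.0
  n <- count_unique_protein_ligands(site, structure, radius)
  if (n < 2 || occ <= 0.5) return("artifact_like")
  if (n >= 3) return("preorganized_3plus")
  "coordinated_2plus"
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure '%s': %d atoms, %d residues, %d LINK records>\n",
              x$id, nrow(x$atoms),
              length(unique(residue_key(x$atoms$chain, x$atoms$resseq, x$atoms$icode))),
              nrow(x$links)))
  invisible(x)
}

# split protein atoms into residues; returns a named list of atom data frames
split_residues <- function(structure, protein_only = TRUE) {
  a <- structure$atoms
  if (protein_only) a <- a[!a$het, , drop = FALSE]
  if (!nrow(a)) return(list())
  key <- residue_key(a$chain, a$resseq, a$icode)
  split(a, factor(key, levels = unique(key)))
}
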