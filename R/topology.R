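#' Read a molecular topology
#'
#' Parses a PDB or GRO file into a light-weight topology: the ordered atom
#' table and the ordered residue list. Residue identity is the pair
#' (chain, residue number); residues appear in file order, chains
#' concatenated as encountered. HETATM records are kept and form their own
#' residues unless excluded downstream via a selection restriction.
#'
#' Coordinates stored in the file are not retained here (a topology is
#' geometry-free); use [read_frames()] for coordinates.
#'
#' @param path path to the structure file.
#' @param dialect `"pdb"`, `"gro"`, or `"auto"` (by file extension).
#' @return An object of class `"topology"`: a list with
#'   \describe{
#'     \item{atoms}{data.frame with `index` (1-based), `name`, `element`,
#'       `residue` (1-based index into `residues`).}
#'     \item{residues}{data.frame with `chain`, `seq`, `name`.}
#'     \item{n_residues}{number of residues.}
#'   }
#' @details Alternate-location indicators other than `' '` or `'A'` are
#'   dropped with a warning. Insertion codes are not supported and raise an
#'   error, so that (chain, residue number) is an unambiguous key.
#' @export
load_topology <- function(path, dialect = c("auto", "pdb", "gro")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "gro") "gro" else "pdb"
  }
  at <- switch(dialect,
    pdb = parse_pdb_atoms(path),
    gro = parse_gro_atoms(path)
  )
  if (nrow(at) == 0L) stop("no atoms found in ", path)
  key <- paste(at$chain, at$resno, sep = "\r")
  ridx <- match(key, unique(key))
  residues <- data.frame(
    chain = at$chain[!duplicated(key)],
    seq = at$resno[!duplicated(key)],
    name = at$resname[!duplicated(key)],
    stringsAsFactors = FALSE
  )
  topo <- structure(list(
    atoms = data.frame(
      index = seq_len(nrow(at)),
      name = at$name,
      element = at$element,
      residue = ridx,
      stringsAsFactors = FALSE
    ),
    residues = residues,
    n_residues = nrow(residues)
  ), class = "topology")
  topo
}

# Fixed-column ATOM/HETATM parser for the first model of a PDB file.
parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # restrict to the first model if MODEL/ENDMDL present
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- which(rec == "ATOM  " | rec == "HETATM")
  if (!length(keep)) {
    return(data.frame(name = character(), element = character(),
                      chain = character(), resno = integer(),
                      resname = character(), stringsAsFactors = FALSE))
  }
  ln <- lines[keep]
  bad <- nchar(ln) < 54
  if (any(bad)) {
    stop("malformed PDB record at line ", keep[which(bad)[1]],
         " (shorter than coordinate columns)")
  }
  alt <- substr(ln, 17, 17)
  drop_alt <- !(alt %in% c(" ", "A", ""))
  if (any(drop_alt)) {
    warning(sum(drop_alt), " alternate-location atoms dropped (kept ' '/'A')")
    ln <- ln[!drop_alt]
    keep <- keep[!drop_alt]
  }
  icode <- trimws(substr(ln, 27, 27))
  if (any(nzchar(icode))) {
    stop("insertion codes are not supported (line ",
         keep[which(nzchar(icode))[1]], ")")
  }
  resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  if (anyNA(resno)) {
    stop("malformed residue number at line ", keep[which(is.na(resno))[1]])
  }
  name <- trimws(substr(ln, 13, 16))
  elem <- trimws(substr(ln, 77, 78))
  noel <- !nzchar(elem)
  if (any(noel)) elem[noel] <- element_from_name(name[noel])
  chain <- substr(ln, 22, 22)
  chain[chain == " "] <- "A"
  data.frame(name = name, element = toupper(elem), chain = chain,
             resno = resno, resname = trimws(substr(ln, 18, 20)),
             stringsAsFactors = FALSE)
}

# GRO fixed columns: resno(1-5) resname(6-10) atomname(11-15) atomno(16-20).
parse_gro_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count at line 2")
  if (length(lines) < 2L + n) stop("GRO file truncated: expected ", n, " atom lines")
  ln <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(ln, 1, 5)))
  if (anyNA(resno)) stop("malformed GRO residue number at line ",
                         2L + which(is.na(resno))[1])
  name <- trimws(substr(ln, 11, 15))
  data.frame(name = name, element = element_from_name(name),
             chain = "A", resno = resno,
             resname = trimws(substr(ln, 6, 10)),
             stringsAsFactors = FALSE)
}

# Heuristic element assignment from an atom name: strip leading digits,
# take the first letter. Covers the H/C/N/O/S/P names used in protein files.
element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  toupper(substr(stripped, 1, 1))
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,", x$n_residues, "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' Resolve an atom-class selection into per-residue atom groups
#'
#' Maps every residue of a topology to the ordered set of atom indices that
#' participate in distance computations, according to the chosen atom class:
#' \describe{
#'   \item{heavy}{all non-hydrogen atoms (the default used throughout).}
#'   \item{c_alpha}{atoms named CA.}
#'   \item{backbone}{heavy atoms named N, CA, C or O.}
#'   \item{side_chain}{heavy atoms that are not backbone (glycine has none).}
#'   \item{all}{every atom, hydrogens included.}
#' }
#' Residues with no selected atom (e.g. glycine under `side_chain`) are
#' flagged inert and take part in no residue pair.
#'
#' @param topology a `"topology"` object.
#' @param atom_class one of `"heavy"`, `"c_alpha"`, `"backbone"`,
#'   `"side_chain"`, `"all"`.
#' @param restrict optional integer vector of 1-based residue indices; all
#'   other residues are made inert (analogous to an index-group file).
#' @return An object of class `"selection_map"`: list with `atoms` (list of
#'   integer vectors, one per residue), `inert` (logical per residue),
#'   `atom_class`.
#' @export
select_atoms <- function(topology,
                         atom_class = c("heavy", "c_alpha", "backbone",
                                        "side_chain", "all"),
                         restrict = NULL) {
  atom_class <- match.arg(atom_class)
  stopifnot(inherits(topology, "topology"))
  a <- topology$atoms
  if (nrow(a) == 0L) stop("empty topology")
  heavy <- a$element != "H"
  bb <- heavy & a$name %in% c("N", "CA", "C", "O")
  pick <- switch(atom_class,
    heavy = heavy,
    c_alpha = a$name == "CA",
    backbone = bb,
    side_chain = heavy & !bb,
    all = rep(TRUE, nrow(a))
  )
  sel <- lapply(seq_len(topology$n_residues), function(r) {
    a$index[pick & a$residue == r]
  })
  if (!is.null(restrict)) {
    restrict <- as.integer(restrict)
    if (any(restrict < 1L | restrict > topology$n_residues)) {
      stop("restriction list contains residue indices outside 1..",
           topology$n_residues)
    }
    sel[setdiff(seq_len(topology$n_residues), restrict)] <-
      list(integer(0))
  }
  inert <- lengths(sel) == 0L
  if (any(inert)) {
    message(sum(inert), " residue(s) inert under atom class '", atom_class, "'")
  }
  structure(list(atoms = sel, inert = inert, atom_class = atom_class),
            class = "selection_map")
}

#' Read a residue restriction list
#'
#' One 1-based residue index per line; blank and `#` lines ignored.
#' @param path file path.
#' @return integer vector of residue indices.
#' @export
read_restriction <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  v <- suppressWarnings(as.integer(ln))
  if (anyNA(v)) stop("non-integer entry in restriction file: ", path)
  v
}
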