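#' Structure and trajectory containers
#'
#' An `md_structure` holds one model of a protein structure: an atom table
#' (serial, name, residue name, author residue id, chain, element, B-factor)
#' and an n x 3 coordinate matrix in Angstrom. Residue ids follow the author
#' numbering of the source file and are never renumbered; gaps are preserved.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `element`, `b`.
#' @param xyz numeric n x 3 matrix of coordinates (Angstrom).
#' @return an object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("xyz must be an n x 3 matrix")
  if (nrow(atoms) != nrow(xyz)) {
    stopf("atom table (%d rows) and coordinates (%d rows) disagree",
          nrow(atoms), nrow(xyz))
  }
  if (!all(is.finite(xyz))) stopf("coordinates must be finite")
  if (!is.null(atoms$b) && any(!is.na(atoms$b) & atoms$b < 0)) {
    stopf("B-factors must be >= 0")
  }
  structure(list(atoms = atoms, xyz = unname(xyz)), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  g <- structure_gaps(x)
  cat(sprintf("md_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = " ")))
  if (nrow(g)) {
    cat(sprintf("  %d residue-numbering gap(s), e.g. %s %d..%d\n",
                nrow(g), g$chain[1], g$before[1], g$after[1]))
  }
  invisible(x)
}

guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  ifelse(grepl("^H", nm) | nm == "", "H", substr(nm, 1, 1))
}

#' Read a PDB structure file
#'
#' Parses ATOM/HETATM records at their fixed column positions. Multi-model
#' files are returned as a list of `md_structure` objects (class
#' `md_ensemble`) sharing one atom table, as used for cross-correlation maps
#' over crystallographic ensembles.
#'
#' @param path path to a PDB-format text file.
#' @return an `md_structure`, or an `md_ensemble` (list of structures) when
#'   the file holds several MODELs.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stopf("no ATOM/HETATM records in %s", path)
  # validate before handing to the parser: coordinates must be present and
  # numeric at columns 31-54
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stopf("malformed ATOM record at line %d of %s: record too short", i, path)
    }
    fields <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(fields))))) {
      stopf("malformed ATOM record at line %d of %s: non-numeric coordinates",
            i, path)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  ele <- a$elesy
  ele[is.na(ele) | trimws(ele) == ""] <- guess_element(a$elety[is.na(ele) | trimws(ele) == ""])
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    resname = trimws(a$resid),
    resid = a$resno,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    element = trimws(ele),
    b = a$b,
    stringsAsFactors = FALSE
  )
  n_models <- nrow(pdb$xyz)
  if (n_models == 1L) {
    return(md_structure(atoms, matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)))
  }
  ens <- lapply(seq_len(n_models), function(m) {
    md_structure(atoms, matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE))
  })
  class(ens) <- "md_ensemble"
  ens
}

#' Write a structure to a PDB file
#'
#' @param x an `md_structure`.
#' @param path output path.
#' @param bfactor optional replacement B-factor vector (Angstrom^2) to stamp
#'   into the B column, e.g. computed values from [rmsf_profile()].
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, bfactor = NULL) {
  stopifnot(inherits(x, "md_structure"))
  b <- bfactor %||% x$atoms$b
  if (is.null(b) || all(is.na(b))) b <- rep(0, nrow(x$atoms))
  b[is.na(b)] <- 0
  bio3d::write.pdb(
    file = path,
    xyz = coords_row(x$xyz),
    resno = x$atoms$resid,
    resid = x$atoms$resname,
    eleno = x$atoms$serial,
    elety = x$atoms$name,
    chain = x$atoms$chain,
    b = b,
    elesy = x$atoms$element
  )
  invisible(path)
}

#' Report residue-numbering gaps
#'
#' Lists places where consecutive residues within a chain jump by more than
#' one in author numbering (e.g. an unresolved loop).
#'
#' @param x an `md_structure`.
#' @return data.frame with columns `chain`, `before`, `after`, `missing`.
#' @export
structure_gaps <- function(x) {
  stopifnot(inherits(x, "md_structure"))
  out <- data.frame(chain = character(), before = integer(), after = integer(),
                    missing = integer(), stringsAsFactors = FALSE)
  for (ch in unique(x$atoms$chain)) {
    r <- sort(unique(x$atoms$resid[x$atoms$chain == ch]))
    if (length(r) < 2) next
    d <- diff(r)
    idx <- which(d > 1)
    if (length(idx)) {
      out <- rbind(out, data.frame(chain = ch, before = r[idx],
                                   after = r[idx + 1], missing = d[idx] - 1L,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
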