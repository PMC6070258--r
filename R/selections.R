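#' Select atoms by a small expression grammar
#'
#' Resolves an atom selection on a structure or trajectory atom table. The
#' grammar is a conjunction of clauses joined by `" and "`; each clause is one
#' of:
#' \describe{
#'   \item{`all`}{every atom}
#'   \item{`name CA,CB`}{atom-name list (comma or space separated)}
#'   \item{`heavy`}{non-hydrogen atoms}
#'   \item{`resid 10-20,35`}{author residue-id ranges and singletons}
#'   \item{`chain A`}{chain id}
#' }
#' A clause may be negated with a leading `not` (e.g. `not resid 1832-2000`
#' to exclude a domain). Residue ids are matched after adding `offset`, so
#' selections written in an alternative numbering scheme can be applied to
#' author numbering without renumbering the structure.
#'
#' @param x an `md_structure`, `md_trajectory`, or atom table.
#' @param expression selection string.
#' @param offset integer added to the expression's residue ids before matching
#'   (default 0).
#' @return an `md_selection`: list with sorted unique `indices` and `label`.
#' @export
select_atoms <- function(x, expression, offset = 0L) {
  atoms <- if (is.data.frame(x)) x else x$atoms
  if (is.null(atoms)) stopf("no atom table available for selection")
  expression <- trimws(expression)
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    cl <- trimws(cl)
    neg <- grepl("^not\\s+", cl)
    if (neg) cl <- sub("^not\\s+", "", cl)
    m <- clause_mask(atoms, cl, offset)
    keep <- keep & (if (neg) !m else m)
  }
  idx <- which(keep)
  if (!length(idx)) stopf("selection '%s' matches no atoms", expression)
  structure(list(indices = as.integer(idx), label = expression),
            class = "md_selection")
}

clause_mask <- function(atoms, cl, offset) {
  if (cl == "all") return(rep(TRUE, nrow(atoms)))
  if (cl == "heavy") return(toupper(atoms$element) != "H")
  if (grepl("^name\\s+", cl)) {
    names <- strsplit(sub("^name\\s+", "", cl), "[,\\s]+")[[1]]
    return(atoms$name %in% names)
  }
  if (grepl("^chain\\s+", cl)) {
    ch <- strsplit(sub("^chain\\s+", "", cl), "[,\\s]+")[[1]]
    return(atoms$chain %in% ch)
  }
  if (grepl("^resid\\s+", cl)) {
    spec <- strsplit(sub("^resid\\s+", "", cl), "[,\\s]+")[[1]]
    ids <- integer()
    for (s in spec) {
      if (grepl("^-?\\d+--?\\d+$", s) || grepl("^\\d+-\\d+$", s)) {
        parts <- as.integer(strsplit(s, "(?<=\\d)-", perl = TRUE)[[1]])
        ids <- c(ids, seq(parts[1], parts[2]))
      } else {
        ids <- c(ids, as.integer(s))
      }
    }
    return(atoms$resid %in% (ids + offset))
  }
  stopf("unrecognised selection clause: '%s'", cl)
}

#' @export
print.md_selection <- function(x, ...) {
  cat(sprintf("md_selection '%s': %d atoms\n", x$label, length(x$indices)))
  invisible(x)
}

# resolve a selection argument: md_selection, integer indices, or expression
resolve_selection <- function(x, sel) {
  if (inherits(sel, "md_selection")) return(sel)
  if (is.numeric(sel)) {
    return(structure(list(indices = as.integer(sort(unique(sel))),
                          label = "indices"), class = "md_selection"))
  }
  if (is.character(sel)) return(select_atoms(x, sel))
  stopf("cannot interpret selection of class %s", class(sel)[1])
}
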