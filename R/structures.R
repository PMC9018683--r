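# Core coordinate containers: structure_model (one set of atomic coordinates)
# and structure_bundle (an ordered set of topologically identical models, e.g.
# the 20-30 refined conformers deposited from an NMR structure calculation).

#' Construct a structure model
#'
#' A `structure_model` is a data frame of atoms with columns `resid` (1-based
#' residue index), `restype` (3-letter code), `atom` (atom name, unique within
#' a residue), `element`, `chain`, and Cartesian coordinates `x`, `y`, `z`
#' in Angstroms.
#'
#' @param atoms data frame with at least `resid`, `restype`, `atom`, `x`, `y`,
#'   `z`; `element` is inferred from atom names when absent and `chain`
#'   defaults to `"A"`.
#' @param model_id integer identifier (used for multi-model PDB output).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("resid", "restype", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$atom)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  atoms$resid <- as.integer(atoms$resid)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("coordinates must be finite")
  if (any(vapply(split(atoms$resid, atoms$chain), is.unsorted, logical(1L))))
    stop("residue indices must be non-decreasing within a chain")
  key <- paste(atoms$chain, atoms$resid, atoms$atom)
  if (anyDuplicated(key)) stop("atom names must be unique within a residue")
  atoms <- atoms[, c("resid", "restype", "atom", "element", "chain", "x", "y", "z")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues (model %d)\n",
              nrow(x$atoms), length(unique(x$atoms$resid)), x$model_id))
  invisible(x)
}

#' Coordinate matrix of a structure model
#'
#' @param model a `structure_model`.
#' @param selection optional selection string (see [parse_selection()]) or
#'   logical/integer index.
#' @return numeric matrix with one row per selected atom and columns x, y, z.
#' @export
coords <- function(model, selection = NULL) {
  a <- model$atoms
  if (!is.null(selection)) a <- a[select_atoms(model, selection), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  stopifnot(nrow(xyz) == nrow(model$atoms))
  model$atoms$x <- xyz[, 1L]; model$atoms$y <- xyz[, 2L]; model$atoms$z <- xyz[, 3L]
  model
}

#' Construct a structure bundle
#'
#' An ordered set of models sharing one topology (identical atom count,
#' ordering, names and residue numbering), as deposited for NMR ensembles.
#'
#' @param models list of `structure_model` objects.
#' @return an object of class `structure_bundle`.
#' @export
structure_bundle <- function(models) {
  stopifnot(is.list(models), length(models) >= 1L)
  ref <- models[[1L]]$atoms
  for (m in models) {
    a <- m$atoms
    if (nrow(a) != nrow(ref) ||
        !identical(a$atom, ref$atom) || !identical(a$resid, ref$resid))
      stop("all models in a bundle must share one topology")
  }
  for (i in seq_along(models)) models[[i]]$model_id <- i
  structure(list(models = models), class = "structure_bundle")
}

#' @export
print.structure_bundle <- function(x, ...) {
  cat(sprintf("structure_bundle: %d models x %d atoms\n",
              length(x$models), nrow(x$models[[1L]]$atoms)))
  invisible(x)
}

#' @export
length.structure_bundle <- function(x) length(x$models)

# ---- PDB I/O (v3.3 fixed columns, MODEL/ENDMDL for bundles) -----------------

fmt_atom_name <- function(name, element) {
  # columns 13-16: element right-justified in 13-14 for 1-letter elements
  if (nchar(name) >= 4L) return(substr(name, 1L, 4L))
  if (nchar(element) == 1L) sprintf(" %-3s", name) else sprintf("%-4s", name)
}

pdb_atom_lines <- function(atoms) {
  n <- nrow(atoms)
  names4 <- vapply(seq_len(n), function(i)
    fmt_atom_name(atoms$atom[i], atoms$element[i]), character(1L))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          (seq_len(n) - 1L) %% 99999L + 1L, names4, atoms$restype,
          substr(atoms$chain, 1L, 1L), atoms$resid,
          atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Write a model or bundle as a PDB file
#'
#' Bundles are written as MODEL/ENDMDL blocks (multi-model PDB).
#'
#' @param x a `structure_model` or `structure_bundle`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  lines <- character(0)
  if (inherits(x, "structure_model")) {
    lines <- c(pdb_atom_lines(x$atoms), "END")
  } else if (inherits(x, "structure_bundle")) {
    for (m in x$models) {
      lines <- c(lines, sprintf("MODEL     %4d", m$model_id),
                 pdb_atom_lines(m$atoms), "ENDMDL")
    }
    lines <- c(lines, "END")
  } else stop("x must be a structure_model or structure_bundle")
  writeLines(lines, path)
  invisible(path)
}

#' Read a PDB file
#'
#' Reads ATOM/HETATM records; multi-model files become bundles.
#'
#' @param path PDB file path.
#' @param as_bundle return a `structure_bundle` even for single-model files.
#' @return a `structure_model` or `structure_bundle`.
#' @export
read_pdb <- function(path, as_bundle = FALSE) {
  lines <- readLines(path)
  rec <- substr(lines, 1L, 6L)
  model_breaks <- which(trimws(rec) == "MODEL")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  parse_block <- function(block) {
    atoms <- data.frame(
      resid = as.integer(substr(block, 23L, 26L)),
      restype = trimws(substr(block, 18L, 20L)),
      atom = trimws(substr(block, 13L, 16L)),
      element = trimws(substr(block, 77L, 78L)),
      chain = substr(block, 22L, 22L),
      x = as.numeric(substr(block, 31L, 38L)),
      y = as.numeric(substr(block, 39L, 46L)),
      z = as.numeric(substr(block, 47L, 54L)),
      stringsAsFactors = FALSE)
    blank <- atoms$element == ""
    if (any(blank)) atoms$element[blank] <- infer_element(atoms$atom[blank])
    atoms
  }
  if (length(model_breaks) == 0L) {
    m <- structure_model(parse_block(lines[is_atom]))
    return(if (as_bundle) structure_bundle(list(m)) else m)
  }
  ends <- which(trimws(rec) == "ENDMDL")
  if (length(ends) != length(model_breaks)) stop("unbalanced MODEL/ENDMDL records")
  models <- lapply(seq_along(model_breaks), function(k) {
    idx <- seq(model_breaks[k] + 1L, ends[k] - 1L)
    idx <- idx[is_atom[idx]]
    structure_model(parse_block(lines[idx]), model_id = k)
  })
  b <- structure_bundle(models)
  if (!as_bundle && length(b) == 1L) b$models[[1L]] else b
}
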