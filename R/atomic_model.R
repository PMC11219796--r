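# Atomic models: ordered heavy atoms with element, mass, coordinates,
# residue and chain identifiers. Parsing is delegated to bio3d; this layer
# filters to heavy protein atoms and attaches masses.

# monoisotopic-free average atomic masses (Da) for elements common in
# protein/cofactor models
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, MN = 54.938,
  CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45, CU = 63.546,
  NI = 58.693, CO = 58.933, MO = 95.95, I = 126.904, F = 18.998,
  BR = 79.904)

#' Construct an atomic model
#'
#' @param atoms data frame with columns `element`, `mass`, `x`, `y`, `z`,
#'   `resno`, `chain` (one row per heavy atom, file order preserved).
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms) {
  req <- c("element", "mass", "x", "y", "z", "resno", "chain")
  if (!all(req %in% names(atoms))) {
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("model must contain at least one atom")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE)),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d heavy atoms, %d residues, chains: %s\n",
              nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

is_atomic_model <- function(x) inherits(x, "atomic_model")

#' Number of atoms / residues in a model
#' @param model an [atomic_model].
#' @return Integer count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' @rdname n_atoms
#' @export
n_residues <- function(model) {
  nrow(unique(model$atoms[, c("chain", "resno")]))
}

coords_matrix <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

element_from_bio3d <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back on the atom-name column: strip digits, take leading letters
    nm <- toupper(gsub("[0-9']", "", trimws(elety[miss])))
    two <- substr(nm, 1, 2)
    el[miss] <- ifelse(two %in% names(ATOMIC_MASSES) & !(substr(nm, 1, 1) %in%
                         c("C", "N", "O", "S", "P", "H")),
                       two, substr(nm, 1, 1))
  }
  el
}

mass_for_elements <- function(el) {
  m <- ATOMIC_MASSES[el]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; assigning carbon mass")
    m[unknown] <- ATOMIC_MASSES[["C"]]
  }
  unname(m)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Retains heavy atoms of standard polymer records (`ATOM`); hydrogens,
#' waters and hetero small molecules are dropped. For multi-model files only
#' the first model is returned (use [read_ensemble] for ensembles).
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param keep_hetero also keep non-water `HETATM` records (default FALSE).
#' @return An [atomic_model].
#' @export
read_atomic_model <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- parse_structure(path)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keep_hetero) {
    keep <- keep | (at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")))
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) > 0) {
    el <- element_from_bio3d(at$elesy, at$elety)
    at <- at[!(el %in% c("H", "D")), , drop = FALSE]
    el <- el[!(el %in% c("H", "D"))]
  }
  if (nrow(at) == 0L) stop("no heavy protein atoms found in ", path)
  ch <- at$chain
  ch[is.na(ch) | ch == ""] <- "A"
  atomic_model(data.frame(
    element = el, mass = mass_for_elements(el),
    x = at$x, y = at$y, z = at$z,
    resno = at$resno, chain = ch, stringsAsFactors = FALSE))
}

parse_structure <- function(path, multi = FALSE) {
  ext <- tolower(tools::file_ext(path))
  out <- tryCatch({
    if (ext == "cif") bio3d::read.cif(path, multi = multi)
    else bio3d::read.pdb(path, multi = multi)
  }, error = function(e) stop("could not parse structure file ", path, ": ",
                              conditionMessage(e)))
  out
}

#' Write a model as PDB with values in the B-factor column
#'
#' Standard route for visualising per-atom scalars (e.g. predicted RMSF) by
#' colouring in molecular viewers.
#'
#' @param model an [atomic_model].
#' @param values numeric vector, one per atom (written as B-factors,
#'   `%6.2f`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_model_bfactor <- function(model, values, path) {
  stopifnot(is_atomic_model(model), length(values) == n_atoms(model))
  at <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000,
    substr(paste0(" ", at$element), 1, 4),
    "GLY", substr(at$chain, 1, 1), at$resno %% 10000,
    at$x, at$y, at$z, 1.00, pmin(pmax(values, -9.99), 999.99), at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
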