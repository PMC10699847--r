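# StructureModel / ResidueModel containers. Kept as plain S3 lists (bio3d
# style): a structure is an ordered list of residues, each residue a named
# list of atom coordinate 3-vectors keyed by PDB atom name.

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1_TO_3 <- structure(names(AA3_TO_1), names = unname(AA3_TO_1))

# Parent mapping for common nonstandard residues; atoms renamed where the
# parent convention differs (MSE selenium -> MET SD).
NONSTANDARD_PARENT <- c(MSE = "MET")

#' Construct a residue model
#'
#' @param name 3-letter amino-acid code (upper case).
#' @param index author residue numbering; an integer, optionally carrying an
#'   insertion code as an attribute via [read_structure()].
#' @param atoms named list of finite numeric 3-vectors (Angstrom), keyed by
#'   PDB atom names (N, CA, C, O, CB, ...).
#' @return an object of class `residue_model`.
#' @export
residue_model <- function(name, index, atoms) {
  if (!is.character(name) || length(name) != 1)
    stop_validation("residue name must be a single 3-letter code")
  if (anyDuplicated(names(atoms)))
    stop_validation("duplicate atom names in residue %s%s", name, index)
  for (nm in names(atoms)) atoms[[nm]] <- check_point(atoms[[nm]], nm)
  structure(list(name = toupper(name), index = as.integer(index),
                 atoms = atoms),
            class = "residue_model")
}

#' Construct a structure model
#'
#' An ordered chain of residues with named atom coordinates; the object all
#' package geometry derives from. Residues missing any of N, CA, C are kept
#' but flagged incomplete; nonstandard residue codes are flagged.
#'
#' @param residues list of [residue_model()] objects, in chain order.
#' @param chain_id single chain identifier string.
#' @return an object of class `structure_model` with elements `residues`,
#'   `chain_id`, `sequence` (one-letter string, `X` for nonstandard),
#'   `incomplete` (logical per residue), `nonstandard` (logical per residue).
#' @export
structure_model <- function(residues, chain_id = "A") {
  if (!length(residues)) stop_validation("structure has no residues")
  for (r in residues) if (!inherits(r, "residue_model"))
    stop_validation("residues must be residue_model objects")
  nm <- vapply(residues, function(r) r$name, "")
  nonstandard <- !(nm %in% STANDARD_AA3)
  incomplete <- vapply(residues, function(r)
    !all(c("N", "CA", "C") %in% names(r$atoms)), NA)
  seq1 <- ifelse(nonstandard, "X", AA3_TO_1[nm])
  structure(list(residues = residues,
                 chain_id = chain_id,
                 sequence = paste(seq1, collapse = ""),
                 incomplete = incomplete,
                 nonstandard = nonstandard),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: chain %s, %d residues\n  %s\n",
              x$chain_id, length(x$residues), x$sequence))
  invisible(x)
}

#' @export
length.structure_model <- function(x) length(x$residues)

#' Coordinates of one named atom across a structure
#'
#' @param s a `structure_model`.
#' @param atom atom name; with `cb_fallback`, "CB" falls back to "CA" where
#'   CB is absent (glycine).
#' @param cb_fallback logical.
#' @return n x 3 matrix, NA rows where the atom is missing.
#' @export
atom_coords <- function(s, atom = "CA", cb_fallback = FALSE) {
  stopifnot(inherits(s, "structure_model"))
  out <- t(vapply(s$residues, function(r) {
    a <- r$atoms[[atom]]
    if (is.null(a) && cb_fallback && atom == "CB") a <- r$atoms[["CA"]]
    if (is.null(a)) rep(NA_real_, 3) else a
  }, numeric(3)))
  rownames(out) <- vapply(s$residues, function(r) as.character(r$index), "")
  out
}

#' Backbone frames of every residue
#'
#' Builds the [build_frame()] rigid frame for each residue with complete
#' N, CA, C backbone.
#'
#' @param s a `structure_model`.
#' @return list of `rigid_frame`, one per residue; NULL where the backbone is
#'   incomplete.
#' @export
backbone_frames <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  lapply(s$residues, function(r) {
    if (!all(c("N", "CA", "C") %in% names(r$atoms))) return(NULL)
    build_frame(r$atoms$N, r$atoms$CA, r$atoms$C)
  })
}

#' Flatten all atom coordinates of a structure
#'
#' @param s a `structure_model`.
#' @param atoms optional character vector restricting which atom names are
#'   kept (in residue order).
#' @return list with `points` (m x 3 matrix), `residue` (owning residue
#'   position, 1-based, length m) and `atom` (atom names, length m).
#' @export
atom_points <- function(s, atoms = NULL) {
  stopifnot(inherits(s, "structure_model"))
  pts <- list(); res <- integer(); anm <- character()
  for (i in seq_along(s$residues)) {
    r <- s$residues[[i]]
    keep <- names(r$atoms)
    if (!is.null(atoms)) keep <- intersect(keep, atoms)
    for (nm in keep) {
      pts[[length(pts) + 1L]] <- r$atoms[[nm]]
      res <- c(res, i)
      anm <- c(anm, nm)
    }
  }
  list(points = do.call(rbind, pts), residue = res, atom = anm)
}

# Atom names shared residue-by-residue between two equal-length structures;
# used when comparing a model against its native.
common_atom_points <- function(a, b) {
  stopifnot(length(a$residues) == length(b$residues))
  pa <- list(); pb <- list(); res <- integer()
  for (i in seq_along(a$residues)) {
    shared <- intersect(names(a$residues[[i]]$atoms),
                        names(b$residues[[i]]$atoms))
    for (nm in shared) {
      pa[[length(pa) + 1L]] <- a$residues[[i]]$atoms[[nm]]
      pb[[length(pb) + 1L]] <- b$residues[[i]]$atoms[[nm]]
      res <- c(res, i)
    }
  }
  list(a = do.call(rbind, pa), b = do.call(rbind, pb), residue = res)
}
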