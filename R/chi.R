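# Side-chain chi torsion definitions: the standard atom quadruples per
# residue type, following the usual rotamer-library convention. Up to four
# chi angles; availability depends on residue chemistry and on which atoms
# are actually present.

CHI_ATOMS <- list(
  ALA = list(),
  GLY = list(),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# chi angles with a pi-periodic ambiguity: the terminal torsion of the
# two-fold symmetric carboxylate/aromatic groups. Positions are chi indices.
CHI_PI_SYMMETRIC <- list(
  ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L
)

#' Number of chi angles a residue type possesses
#'
#' @param name 3-letter amino-acid code.
#' @return integer in 0..4.
#' @export
n_chi <- function(name) {
  def <- CHI_ATOMS[[toupper(name)]]
  if (is.null(def)) stop_validation("unknown residue type '%s'", name)
  length(def)
}

#' Extract the chi torsion angles of one residue
#'
#' Computes chi1..chi4 from the standard chi-defining atom quadruples for the
#' residue type. Angles whose residue chemistry lacks them, or whose defining
#' atoms are missing, are flagged unavailable (never zero-filled). The
#' pi-periodic terminal torsions of ASP, GLU, PHE and TYR are marked in the
#' `symmetric` flags so callers can apply the alternative-torsion correction.
#'
#' @param residue a [residue_model()] for a standard amino acid.
#' @return list with `chi` (length-4 radians, NA where unavailable), `mask`
#'   (length-4 logical availability) and `symmetric` (length-4 logical);
#'   missing chi-defining atoms add entries to the `warnings` character
#'   vector.
#' @export
extract_chi <- function(residue) {
  stopifnot(inherits(residue, "residue_model"))
  def <- CHI_ATOMS[[residue$name]]
  if (is.null(def))
    stop_validation("residue %s is not a standard amino acid", residue$name)
  chi <- rep(NA_real_, 4)
  mask <- rep(FALSE, 4)
  warnings <- character()
  for (k in seq_along(def)) {
    quad <- def[[k]]
    if (!all(quad %in% names(residue$atoms))) {
      missing <- setdiff(quad, names(residue$atoms))
      warnings <- c(warnings, sprintf(
        "%s%d: chi%d unavailable, missing atom(s) %s",
        residue$name, residue$index, k, paste(missing, collapse = ",")))
      next
    }
    chi[k] <- dihedral(residue$atoms[[quad[1]]], residue$atoms[[quad[2]]],
                       residue$atoms[[quad[3]]], residue$atoms[[quad[4]]])
    mask[k] <- TRUE
  }
  symmetric <- rep(FALSE, 4)
  sym_k <- CHI_PI_SYMMETRIC[[residue$name]]
  if (!is.null(sym_k)) symmetric[sym_k] <- TRUE
  list(chi = chi, mask = mask, symmetric = symmetric, warnings = warnings)
}

#' Per-residue chi torsions of a whole structure
#'
#' Runs [extract_chi()] over every residue and assembles the result into a
#' `torsion_set`.
#'
#' @param s a `structure_model`.
#' @return a [torsion_set()].
#' @export
structure_torsions <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  n <- length(s$residues)
  chi <- matrix(NA_real_, n, 4)
  mask <- matrix(FALSE, n, 4)
  symmetric <- matrix(FALSE, n, 4)
  warnings <- character()
  for (i in seq_len(n)) {
    r <- s$residues[[i]]
    if (!(r$name %in% STANDARD_AA3)) {
      warnings <- c(warnings,
                    sprintf("%s%d: nonstandard residue skipped", r$name, r$index))
      next
    }
    ex <- extract_chi(r)
    chi[i, ] <- ex$chi
    mask[i, ] <- ex$mask
    symmetric[i, ] <- ex$symmetric
    warnings <- c(warnings, ex$warnings)
  }
  torsion_set(chi, mask, symmetric, warnings = warnings)
}

#' Per-residue chi torsion container
#'
#' Holds chi1..chi4 for each residue together with availability and
#' pi-symmetry masks. Angles live in (-pi, pi]; masked entries are NA and are
#' never read by downstream code.
#'
#' @param chi n x 4 numeric matrix of angles in radians (NA where masked).
#' @param mask n x 4 logical availability matrix.
#' @param symmetric n x 4 logical matrix flagging pi-periodic torsions.
#' @param warnings character vector of extraction warnings.
#' @return an object of class `torsion_set`.
#' @export
torsion_set <- function(chi, mask, symmetric = NULL, warnings = character()) {
  chi <- as.matrix(chi); mask <- as.matrix(mask)
  if (ncol(chi) != 4 || !all(dim(chi) == dim(mask)))
    stop_validation("chi and mask must be n x 4 matrices of equal shape")
  if (is.null(symmetric)) symmetric <- matrix(FALSE, nrow(chi), 4)
  if (any(mask & !is.finite(chi)))
    stop_validation("available chi entries must be finite")
  chi[mask] <- wrap_angle(chi[mask])
  chi[!mask] <- NA_real_
  structure(list(chi = chi, mask = mask, symmetric = as.matrix(symmetric),
                 warnings = warnings),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("torsion_set: %d residues, %d available chi angles\n",
              nrow(x$chi), sum(x$mask)))
  invisible(x)
}

# Circular chi difference pred - true, optionally taking the smaller of the
# two pi-related alternatives for flagged symmetric torsions.
chi_difference <- function(chi_true, chi_pred, symmetric = FALSE,
                           symmetry_correct = FALSE) {
  d <- wrap_angle(chi_pred - chi_true)
  if (symmetry_correct && any(symmetric)) {
    d2 <- wrap_angle(chi_pred + pi - chi_true)
    swap <- symmetric & (abs(d2) < abs(d))
    d[swap] <- d2[swap]
  }
  d
}

check_same_masks <- function(a, b) {
  if (!identical(dim(a$chi), dim(b$chi)))
    stop_validation("torsion sets have different residue counts")
  if (!identical(a$mask, b$mask))
    stop_validation("torsion sets have mismatching availability masks")
}
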