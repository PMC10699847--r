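# Deterministic synthetic peptides: backbone from ideal internal geometry at
# canonical (phi, psi), side chains grown by NeRF placement with known chi
# torsions. Every loss and metric in the package is testable against these
# with no external data.

# Ideal backbone stereochemistry (Angstrom / degrees), standard
# Engh-Huber-style values.
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

CANONICAL_PHIPSI <- list(
  helix = c(phi = -57, psi = -47),
  extended = c(phi = -139, psi = 135)
)

# Side-chain growth recipes: each atom is NeRF-placed from the three earlier
# atoms of its chi quadruple, at the given bond length (A) and angle (deg),
# with the torsion set to the residue's chi_k. CB is placed separately.
SIDE_CHAIN_RECIPE <- list(
  ALA = list(), GLY = list(),
  SER = list(list("OG",  c("N", "CA", "CB"),  1.417, 110.8, 1L)),
  CYS = list(list("SG",  c("N", "CA", "CB"),  1.808, 114.4, 1L)),
  THR = list(list("OG1", c("N", "CA", "CB"),  1.433, 109.6, 1L)),
  VAL = list(list("CG1", c("N", "CA", "CB"),  1.527, 110.5, 1L)),
  ILE = list(list("CG1", c("N", "CA", "CB"),  1.530, 110.4, 1L),
             list("CD1", c("CA", "CB", "CG1"), 1.513, 113.8, 2L)),
  LEU = list(list("CG",  c("N", "CA", "CB"),  1.530, 116.3, 1L),
             list("CD1", c("CA", "CB", "CG"), 1.521, 110.5, 2L)),
  ASN = list(list("CG",  c("N", "CA", "CB"),  1.516, 112.7, 1L),
             list("OD1", c("CA", "CB", "CG"), 1.231, 120.8, 2L)),
  ASP = list(list("CG",  c("N", "CA", "CB"),  1.516, 112.7, 1L),
             list("OD1", c("CA", "CB", "CG"), 1.249, 118.5, 2L)),
  GLN = list(list("CG",  c("N", "CA", "CB"),  1.520, 114.1, 1L),
             list("CD",  c("CA", "CB", "CG"), 1.516, 112.7, 2L),
             list("OE1", c("CB", "CG", "CD"), 1.231, 120.8, 3L)),
  GLU = list(list("CG",  c("N", "CA", "CB"),  1.520, 114.1, 1L),
             list("CD",  c("CA", "CB", "CG"), 1.516, 112.7, 2L),
             list("OE1", c("CB", "CG", "CD"), 1.249, 118.5, 3L)),
  MET = list(list("CG",  c("N", "CA", "CB"),  1.520, 114.1, 1L),
             list("SD",  c("CA", "CB", "CG"), 1.803, 112.7, 2L),
             list("CE",  c("CB", "CG", "SD"), 1.791, 100.2, 3L)),
  LYS = list(list("CG",  c("N", "CA", "CB"),  1.520, 114.1, 1L),
             list("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 2L),
             list("CE",  c("CB", "CG", "CD"), 1.520, 111.3, 3L),
             list("NZ",  c("CG", "CD", "CE"), 1.489, 111.9, 4L)),
  ARG = list(list("CG",  c("N", "CA", "CB"),  1.520, 114.1, 1L),
             list("CD",  c("CA", "CB", "CG"), 1.520, 111.3, 2L),
             list("NE",  c("CB", "CG", "CD"), 1.460, 112.0, 3L),
             list("CZ",  c("CG", "CD", "NE"), 1.329, 124.2, 4L)),
  HIS = list(list("CG",  c("N", "CA", "CB"),  1.504, 113.8, 1L),
             list("ND1", c("CA", "CB", "CG"), 1.378, 122.7, 2L)),
  PHE = list(list("CG",  c("N", "CA", "CB"),  1.502, 113.8, 1L),
             list("CD1", c("CA", "CB", "CG"), 1.384, 120.7, 2L)),
  TYR = list(list("CG",  c("N", "CA", "CB"),  1.512, 113.9, 1L),
             list("CD1", c("CA", "CB", "CG"), 1.387, 120.9, 2L)),
  TRP = list(list("CG",  c("N", "CA", "CB"),  1.498, 113.6, 1L),
             list("CD1", c("CA", "CB", "CG"), 1.365, 126.9, 2L)),
  PRO = list(list("CG",  c("N", "CA", "CB"),  1.492, 104.5, 1L),
             list("CD",  c("CA", "CB", "CG"), 1.503, 105.5, 2L))
)

# Idealized CB position from the backbone N, CA, C (right-handed
# L-amino-acid geometry).
place_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc + ca
}

grow_side_chain <- function(name, atoms, chi) {
  recipe <- SIDE_CHAIN_RECIPE[[name]]
  if (name != "GLY")
    atoms$CB <- place_cb(atoms$N, atoms$CA, atoms$C)
  for (step in recipe) {
    prev <- step[[2]]
    atoms[[step[[1]]]] <- place_atom(atoms[[prev[1]]], atoms[[prev[2]]],
                                     atoms[[prev[3]]], step[[3]],
                                     deg2rad(step[[4]]), chi[step[[5]]])
  }
  atoms
}

#' Build a synthetic peptide with known torsions
#'
#' Constructs an ideal-geometry backbone at the canonical (phi, psi) of the
#' requested conformation (helix: -57/-47, extended: -139/135, omega 180)
#' and grows side chains by NeRF placement with chi angles drawn uniformly
#' on (-pi, pi] (seed-reproducible) or supplied explicitly. The drawn
#' torsions are recorded on the result, so build/extract round trips are
#' exact up to floating-point error.
#'
#' @param sequence one-letter amino-acid string (standard residues only).
#' @param conformation "helix" or "extended".
#' @param seed integer seed for the chi draw.
#' @param chi optional n x 4 matrix of chi angles (radians) overriding the
#'   random draw; NA entries where the residue lacks that chi.
#' @return a `structure_model`; `attr(, "torsions")` holds the generating
#'   [torsion_set()].
#' @export
make_peptide <- function(sequence, conformation = c("helix", "extended"),
                         seed = 1, chi = NULL) {
  conformation <- match.arg(conformation)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop_validation("empty sequence")
  bad <- setdiff(letters1, names(AA1_TO_3))
  if (length(bad))
    stop_validation("invalid amino-acid letter(s): %s",
                    paste(unique(bad), collapse = ", "))
  aa3 <- AA1_TO_3[letters1]
  n_res <- length(aa3)
  pp <- CANONICAL_PHIPSI[[conformation]]
  phi <- deg2rad(pp["phi"]); psi <- deg2rad(pp["psi"])

  # chi angles: supplied, or uniform draw over each residue's available set
  nchi <- unname(vapply(aa3, n_chi, 1L))
  mask <- outer(nchi, 1:4, ">=")
  if (is.null(chi)) {
    set.seed(seed)
    chi <- matrix(NA_real_, n_res, 4)
    draws <- wrap_angle(stats::runif(sum(mask), -pi, pi))
    chi[mask] <- draws
  } else {
    chi <- as.matrix(chi)
    if (!all(dim(chi) == c(n_res, 4)))
      stop_validation("chi must be a %d x 4 matrix", n_res)
    if (any(mask & !is.finite(chi)))
      stop_validation("chi missing for an available torsion")
    chi[mask] <- wrap_angle(chi[mask])
    chi[!mask] <- NA_real_
  }

  g <- BB_GEOM
  bb <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    if (i == 1) {
      n <- c(0, 0, 0)
      ca <- c(g$n_ca, 0, 0)
      alpha <- pi - deg2rad(g$ang_n_ca_c)
      cc <- ca + g$ca_c * c(cos(alpha), sin(alpha), 0)
    } else {
      p <- bb[[i - 1]]
      n <- place_atom(p$N, p$CA, p$C, g$c_n, deg2rad(g$ang_ca_c_n), psi)
      ca <- place_atom(p$CA, p$C, n, g$n_ca, deg2rad(g$ang_c_n_ca), pi)
      cc <- place_atom(p$C, n, ca, g$ca_c, deg2rad(g$ang_n_ca_c), phi)
    }
    o <- place_atom(n, ca, cc, g$c_o, deg2rad(g$ang_ca_c_o),
                    wrap_angle(psi + pi))
    bb[[i]] <- list(N = n, CA = ca, C = cc, O = o)
  }

  residues <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    atoms <- grow_side_chain(aa3[i], bb[[i]], chi[i, ])
    residues[[i]] <- residue_model(aa3[i], i, atoms)
  }
  s <- structure_model(residues)
  sym <- matrix(FALSE, n_res, 4)
  for (i in seq_len(n_res)) {
    k <- CHI_PI_SYMMETRIC[[aa3[i]]]
    if (!is.null(k)) sym[i, k] <- TRUE
  }
  attr(s, "torsions") <- torsion_set(chi, mask, sym)
  s
}

#' Perturb side-chain torsions with wrapped-Gaussian noise
#'
#' Rotates every available chi of a generated peptide by wrapped-Gaussian
#' noise and regrows the distal side-chain atoms accordingly. The applied
#' deltas are recorded, so downstream confidence and accuracy statistics can
#' be checked against exact ground truth.
#'
#' @param s a `structure_model` built by [make_peptide()] (the side-chain
#'   growth recipe must apply).
#' @param sigma_deg noise scale in degrees; a scalar or length-4 vector
#'   (per chi).
#' @param seed integer seed.
#' @return a perturbed `structure_model`; `attr(, "torsions")` holds the new
#'   generating torsions and `attr(, "delta")` the n x 4 matrix of applied
#'   (wrapped) chi changes in radians.
#' @export
perturb_chi <- function(s, sigma_deg = 10, seed = 1) {
  stopifnot(inherits(s, "structure_model"))
  ts <- attr(s, "torsions")
  if (is.null(ts)) ts <- structure_torsions(s)
  sigma <- deg2rad(rep_len(sigma_deg, 4))
  n_res <- nrow(ts$chi)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_res * 4), n_res, 4) *
    matrix(sigma, n_res, 4, byrow = TRUE)
  delta <- matrix(0, n_res, 4)
  delta[ts$mask] <- noise[ts$mask]
  new_chi <- ts$chi
  new_chi[ts$mask] <- wrap_angle(ts$chi[ts$mask] + delta[ts$mask])
  wrapped_delta <- matrix(0, n_res, 4)
  wrapped_delta[ts$mask] <-
    wrap_angle(new_chi[ts$mask] - ts$chi[ts$mask])

  residues <- s$residues
  for (i in seq_len(n_res)) {
    r <- residues[[i]]
    atoms <- r$atoms[intersect(c("N", "CA", "C", "O"), names(r$atoms))]
    atoms <- grow_side_chain(r$name, atoms, new_chi[i, ])
    residues[[i]] <- residue_model(r$name, r$index, atoms)
  }
  out <- structure_model(residues, chain_id = s$chain_id)
  attr(out, "torsions") <- torsion_set(new_chi, ts$mask, ts$symmetric)
  attr(out, "delta") <- wrapped_delta
  out
}

# Random rotation matrix with the given rotation angle (radians) about a
# uniformly random axis.
random_rotation <- function(angle) {
  ax <- stats::rnorm(3)
  ax <- ax / vnorm(ax)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Jitter per-residue rigid placement
#'
#' Applies an independent small rigid motion to every residue: a random
#' rotation about its CA plus a Gaussian translation, calibrated so the
#' translation component alone gives the requested coordinate RMSD (the
#' rotational component adds a small extra displacement on distal atoms).
#' A target of 0 returns the structure unchanged.
#'
#' @param s a `structure_model`.
#' @param rmsd_target target coordinate displacement in Angstrom.
#' @param seed integer seed.
#' @param rot_scale rotation-angle standard deviation per Angstrom of target
#'   (radians, default 0.05).
#' @return a perturbed `structure_model`.
#' @export
perturb_rigid <- function(s, rmsd_target, seed = 1, rot_scale = 0.05) {
  stopifnot(inherits(s, "structure_model"))
  if (rmsd_target < 0) stop_validation("rmsd_target must be non-negative")
  if (rmsd_target == 0) return(s)
  set.seed(seed)
  sigma_t <- rmsd_target / sqrt(3)
  sigma_a <- min(0.5, rot_scale * rmsd_target)
  residues <- s$residues
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    ca <- r$atoms$CA
    if (is.null(ca)) next
    rot <- random_rotation(stats::rnorm(1, 0, sigma_a))
    shift <- stats::rnorm(3, 0, sigma_t)
    atoms <- lapply(r$atoms, function(x)
      as.numeric(rot %*% (x - ca)) + ca + shift)
    residues[[i]] <- residue_model(r$name, r$index, atoms)
  }
  structure_model(residues, chain_id = s$chain_id)
}
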