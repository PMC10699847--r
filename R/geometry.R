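#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by the three consecutive bond vectors
#' p1->p2, p2->p3, p3->p4, using the IUPAC sign convention: the cis (eclipsed)
#' arrangement is 0, trans is +pi, and the sign is positive for a clockwise
#' rotation of the far bond when sighting along p2->p3.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return a single angle in radians, in (-pi, pi].
#' @details Degenerate geometry (a zero-length bond or exactly collinear
#'   atoms) raises a geometry error rather than returning a silent 0.
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # cis: 0
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # trans: pi
#' @export
dihedral <- function(p1, p2, p3, p4) {
  p1 <- check_point(p1, "p1"); p2 <- check_point(p2, "p2")
  p3 <- check_point(p3, "p3"); p4 <- check_point(p4, "p4")
  b0 <- p1 - p2
  b1 <- p3 - p2
  b2 <- p4 - p3
  nb1 <- vnorm(b1)
  if (vnorm(b0) < 1e-9 || nb1 < 1e-9 || vnorm(b2) < 1e-9)
    stop_geometry("degenerate dihedral: zero-length bond vector")
  b1u <- b1 / nb1
  # project b0 and b2 onto the plane perpendicular to the central bond
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  if (vnorm(v) < 1e-9 || vnorm(w) < 1e-9)
    stop_geometry("degenerate dihedral: collinear atoms")
  x <- sum(v * w)
  y <- sum(cross3(b1u, v) * w)
  wrap_angle(atan2(y, x))
}

#' Rigid-body transform (rotation + translation)
#'
#' A per-residue rigid frame: a 3x3 rotation taking local to global
#' coordinates and a translation (the frame origin) in Angstrom. Frames are
#' closed under composition and inversion.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (to 1e-6).
#' @param translation numeric 3-vector, Angstrom.
#' @return an object of class `rigid_frame`.
#' @export
rigid_frame <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3, 3)) ||
      !all(is.finite(rotation)))
    stop_validation("rotation must be a finite 3x3 matrix")
  translation <- check_point(translation, "translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop_validation("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_frame")
}

#' @export
print.rigid_frame <- function(x, ...) {
  cat("rigid_frame\n  translation:", format(x$translation, digits = 4), "\n")
  print(round(x$rotation, 4))
  invisible(x)
}

#' Compose two rigid frames
#'
#' `rigid_compose(a, b)` is the transform applying `b` first, then `a`.
#'
#' @param a,b `rigid_frame` objects.
#' @return a `rigid_frame`.
#' @export
rigid_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_frame"), inherits(b, "rigid_frame"))
  rigid_frame(a$rotation %*% b$rotation,
              as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid frame
#'
#' @param frame a `rigid_frame`.
#' @return the inverse transform, also a `rigid_frame`.
#' @export
rigid_invert <- function(frame) {
  stopifnot(inherits(frame, "rigid_frame"))
  rt <- t(frame$rotation)
  rigid_frame(rt, as.numeric(-rt %*% frame$translation))
}

#' Apply a rigid frame to points
#'
#' Maps each point x to R x + t.
#'
#' @param frame a `rigid_frame`.
#' @param points a numeric 3-vector or an n x 3 matrix of row points.
#' @return transformed points with the same shape as the input.
#' @export
apply_rigid <- function(frame, points) {
  stopifnot(inherits(frame, "rigid_frame"))
  if (is.null(dim(points))) {
    points <- check_point(points, "points")
    return(as.numeric(frame$rotation %*% points) + frame$translation)
  }
  if (ncol(points) != 3) stop_validation("points must be an n x 3 matrix")
  sweep(points %*% t(frame$rotation), 2, frame$translation, "+")
}

#' Backbone rigid frame from N, CA, C coordinates
#'
#' Builds the standard backbone frame by Gram-Schmidt on the N, CA, C atoms:
#' the origin is CA, the first axis points along CA->C, the second axis is
#' CA->N orthogonalized against the first, and the third completes a
#' right-handed system. The returned rotation maps local to global
#' coordinates, so the frame inverse expresses global points in residue-local
#' coordinates (C on the +x axis, N in the xy-plane).
#'
#' @param n,ca,c backbone atom coordinates, numeric 3-vectors in Angstrom.
#' @return a `rigid_frame` with translation = `ca`.
#' @examples
#' f <- build_frame(n = c(-0.5, 1.3, 0), ca = c(0, 0, 0), c = c(1.5, 0, 0))
#' f$rotation  # identity: canonical placement
#' @export
build_frame <- function(n, ca, c) {
  n <- check_point(n, "n"); ca <- check_point(ca, "ca")
  c <- check_point(c, "c")
  v1 <- c - ca
  v2 <- n - ca
  if (vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9)
    stop_geometry("coincident backbone atoms")
  e1 <- v1 / vnorm(v1)
  u2 <- v2 - sum(v2 * e1) * e1
  if (vnorm(u2) < 1e-9)
    stop_geometry("collinear backbone atoms: frame undefined")
  e2 <- u2 / vnorm(u2)
  e3 <- cross3(e1, e2)
  rigid_frame(cbind(e1, e2, e3, deparse.level = 0), ca)
}

# NeRF (natural extension reference frame) placement: position atom D given
# the three preceding atoms A, B, C, the C-D bond length, the B-C-D bond
# angle and the A-B-C-D torsion. Sign convention matches dihedral().
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bcu <- unitv(bc)
  nu <- unitv(cross3(b - a, bcu))
  mu <- cross3(nu, bcu)
  d2 <- bond * c(-cos(angle),
                 sin(angle) * cos(torsion),
                 sin(angle) * sin(torsion))
  c + d2[1] * bcu + d2[2] * mu + d2[3] * nu
}
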