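# Independent oracles and small generators used across the suite. These are
# deliberately coded from first principles, separate from the package
# implementations they check.

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Two-plane-normal construction of the signed dihedral: normals of the
# (p1,p2,p3) and (p2,p3,p4) planes, angle between them signed by the central
# bond direction.
dihedral_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- xprod(b1, b2)
  n2 <- xprod(b2, b3)
  b2u <- b2 / sqrt(sum(b2^2))
  atan2(sum(xprod(n1, n2) * b2u), sum(n1 * n2))
}

# Brute-force alignment-quality ratio: enumerate every native residue pair
# directly from coordinates, with its own distance computation and pair
# bookkeeping.
alignment_quality_oracle <- function(native, template, aln, min_sep = 4,
                                     native_cutoff = 8, sim_threshold = 3) {
  cb <- function(s) t(vapply(s$residues, function(r) {
    if (!is.null(r$atoms$CB)) r$atoms$CB else r$atoms$CA
  }, numeric(3)))
  cn <- cb(native)
  ct <- cb(template)
  idx <- vapply(native$residues, function(r) r$index, 1L)
  lookup <- rep(NA_integer_, length(native$residues))
  if (nrow(aln$pairs)) lookup[aln$pairs[, 1]] <- aln$pairs[, 2]
  collected <- 0
  similar <- 0
  n <- nrow(cn)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (abs(idx[i] - idx[j]) < min_sep) next
    dn <- sqrt(sum((cn[i, ] - cn[j, ])^2))
    if (dn >= native_cutoff) next
    collected <- collected + 1
    if (!is.na(lookup[i]) && !is.na(lookup[j])) {
      dt <- sqrt(sum((ct[lookup[i], ] - ct[lookup[j], ])^2))
      if (abs(dn - dt) < sim_threshold) similar <- similar + 1
    }
  }
  if (collected == 0) stop("oracle: empty pair set")
  similar / collected
}

random_rigid <- function() {
  # rotation via QR of a random Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  rigid_frame(q, rnorm(3, sd = 20))
}

random_points <- function(n, sd = 10) matrix(rnorm(3 * n, sd = sd), n, 3)

# A sequence exercising every residue type and chi depth
ALL_AA_SEQ <- "ARNDCQEGHILKMFPSTWYV"
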