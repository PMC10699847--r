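# Distance-bin probability handling. A distogram assigns every residue pair
# (i, j) a probability distribution over binned Cbeta-Cbeta distances; the
# mode distance matrix extracted from it drives the weighted-FAPE pair
# weights.

#' Default distogram bin edges
#'
#' 63 edges from 2.3125 to 21.6875 Angstrom in steps of 0.3125, giving 64
#' bins: one below the first edge, 62 interior bins, and an open-ended last
#' bin (the convention of the standard prediction-network distogram head).
#'
#' @return numeric vector of ascending edges in Angstrom.
#' @export
default_bin_edges <- function() seq(2.3125, 21.6875, by = 0.3125)

#' Distogram container
#'
#' @param bin_edges strictly increasing bin edges in Angstrom; edges e1..em
#'   define m + 1 bins: (-Inf, e1), [e1, e2), ..., [em, Inf).
#' @param probs n x n x (m + 1) array; probs[i, j, ] is the bin distribution
#'   for residue pair (i, j). Must be symmetric in (i, j) and row-normalized,
#'   both within 1e-6.
#' @return an object of class `distogram` with fields `n`, `bin_edges`,
#'   `probs`.
#' @export
distogram <- function(bin_edges, probs) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop_validation("bin_edges must be at least 2 strictly increasing values")
  if (length(dim(probs)) != 3 || dim(probs)[1] != dim(probs)[2])
    stop_validation("probs must be an n x n x n_bins array")
  if (dim(probs)[3] != length(bin_edges) + 1)
    stop_validation("probs needs %d bins for %d edges",
                    length(bin_edges) + 1, length(bin_edges))
  n <- dim(probs)[1]
  sums <- apply(probs, c(1, 2), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop_validation("each (i, j) bin distribution must sum to 1")
  asym <- max(abs(probs - aperm(probs, c(2, 1, 3))))
  if (asym > 1e-6)
    stop_validation("distogram must be symmetric in (i, j); max asymmetry %.2g",
                    asym)
  structure(list(n = n, bin_edges = bin_edges, probs = probs),
            class = "distogram")
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("distogram: %d residues, %d bins (%.4g - %.4g A)\n",
              x$n, length(x$bin_edges) + 1, min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

# Representative distance per bin: interior bins use midpoints; the
# unbounded first/last bins extrapolate by half the adjacent bin width
# (floored at 0).
bin_representatives <- function(bin_edges) {
  m <- length(bin_edges)
  w_first <- bin_edges[2] - bin_edges[1]
  w_last <- bin_edges[m] - bin_edges[m - 1]
  c(max(0, bin_edges[1] - w_first / 2),
    (bin_edges[-m] + bin_edges[-1]) / 2,
    bin_edges[m] + w_last / 2)
}

#' Mode distance matrix container
#'
#' @param d n x n symmetric non-negative matrix of distances in Angstrom;
#'   zero diagonal by convention.
#' @return an object of class `mode_distance_matrix`.
#' @export
mode_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(!is.finite(d)) || any(d < 0))
    stop_validation("mode distances must form a finite non-negative square matrix")
  if (max(abs(d - t(d))) > 1e-9)
    stop_validation("mode distance matrix must be symmetric")
  diag(d) <- 0
  structure(list(d = d), class = "mode_distance_matrix")
}

#' Extract the mode distance matrix from a distogram
#'
#' For each residue pair, the representative distance of the bin with the
#' highest probability: interior bins map to their midpoints, the open-ended
#' last bin to the last edge plus half the previous bin width. Ties break
#' toward the lower bin index. The diagonal is set to 0 by convention.
#'
#' @param dg a [distogram()].
#' @return a [mode_distance_matrix()].
#' @export
mode_distance <- function(dg) {
  stopifnot(inherits(dg, "distogram"))
  rep_d <- bin_representatives(dg$bin_edges)
  n <- dg$n
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d[i, j] <- rep_d[which.max(dg$probs[i, j, ])]
  }
  mode_distance_matrix(d)
}

#' Cbeta coordinates (CA fallback for glycine)
#'
#' @param s a `structure_model`.
#' @return n x 3 matrix of Cbeta positions, using CA where CB is absent.
#' @export
cbeta_coords <- function(s) atom_coords(s, "CB", cb_fallback = TRUE)

#' Synthesize a distogram from a known structure
#'
#' Builds per-pair bin probabilities by integrating a Gaussian centered on
#' the true Cbeta-Cbeta distance (CA fallback) over each bin; `sharpness` is
#' the reciprocal of the Gaussian standard deviation in Angstrom, so as
#' sharpness grows the distribution approaches a one-hot on the bin
#' containing the true distance. Optional uniform noise (mixed in with weight
#' `noise`, re-normalized) is drawn reproducibly from `seed`.
#'
#' @param s a `structure_model` (every residue needs CB or CA).
#' @param bin_edges bin edges (default [default_bin_edges()]).
#' @param sharpness positive; 1/sigma of the Gaussian in 1/Angstrom.
#' @param noise mixture weight in [0, 1) of a uniform component (default 0).
#' @param seed integer seed used when `noise > 0`.
#' @return a [distogram()].
#' @export
distogram_from_structure <- function(s, bin_edges = default_bin_edges(),
                                     sharpness = 4, noise = 0, seed = 1) {
  stopifnot(inherits(s, "structure_model"))
  if (sharpness <= 0) stop_validation("sharpness must be positive")
  if (noise < 0 || noise >= 1) stop_validation("noise must lie in [0, 1)")
  cb <- cbeta_coords(s)
  if (anyNA(cb)) stop_validation("structure lacks CB/CA for some residue")
  n <- nrow(cb)
  dmat <- as.matrix(stats::dist(cb))
  nb <- length(bin_edges) + 1
  lo <- c(-Inf, bin_edges)
  hi <- c(bin_edges, Inf)
  sigma <- 1 / sharpness
  probs <- array(0, c(n, n, nb))
  eps <- if (noise > 0) {
    set.seed(seed)
    u <- matrix(stats::runif(n * n), n, n)
    (u + t(u)) / 2   # keep (i, j) symmetry
  } else NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    p <- stats::pnorm(hi, dmat[i, j], sigma) - stats::pnorm(lo, dmat[i, j], sigma)
    if (sum(p) < 1e-12) { # fully outside the binned range numerically
      p <- numeric(nb)
      p[findInterval(dmat[i, j], bin_edges) + 1] <- 1
    }
    p <- p / sum(p)
    if (!is.null(eps)) {
      p <- (1 - noise * eps[i, j]) * p + noise * eps[i, j] / nb
      p <- p / sum(p)
    }
    probs[i, j, ] <- p
  }
  distogram(bin_edges, probs)
}
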