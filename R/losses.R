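# Structure-level training losses: the sequentially conditioned side-chain
# torsion loss, clamped and distogram-weighted FAPE, 8-state secondary
# structure cross-entropy, binned side-chain confidence cross-entropy, and
# their weighted combination.

PROB_FLOOR <- 1e-8

SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "-")

#' Unit-circle representation of an angle
#'
#' @param chi angle(s) in radians.
#' @return for a scalar, a length-2 vector (cos chi, sin chi); for a vector,
#'   an n x 2 matrix. Always unit rows.
#' @export
angle_unit_vector <- function(chi) {
  if (!all(is.finite(chi))) stop_validation("angle must be finite")
  if (length(chi) == 1) return(c(cos(chi), sin(chi)))
  cbind(cos(chi), sin(chi))
}

#' Chord-distance error between two angles
#'
#' The Euclidean norm of the difference of the two unit-circle vectors
#' (cos, sin): equal angles give 0, angles pi apart give 2. Equals
#' 2 sin(|delta|/2) for circular difference delta.
#'
#' @param alpha_true,alpha_pred length-2 unit vectors from
#'   [angle_unit_vector()], or n x 2 matrices of unit rows.
#' @return error value(s) in [0, 2].
#' @export
chi_error <- function(alpha_true, alpha_pred) {
  if (is.null(dim(alpha_true))) {
    return(min(vnorm(alpha_true - alpha_pred), 2))
  }
  d <- alpha_true - alpha_pred
  pmin(sqrt(rowSums(d * d)), 2)
}

#' Sequentially conditioned torsion errors
#'
#' Propagates per-chi errors down the side chain: the error of chi(k)
#' accumulates the error already made at chi(k-1), since the 3D position of
#' later side-chain atoms depends on all earlier torsions. The recursion is
#' t1 = e1, tk = t(k-1) + ek - t(k-1) * ek / 2, which is bounded in [0, 2],
#' monotone in both arguments and dominates both (2 is an absorbing fixed
#' point: a chi(k-1) that is maximally wrong makes every later torsion
#' maximally wrong no matter how accurate it is on its own).
#'
#' @param e length-4 numeric of per-chi errors in [0, 2] (NA allowed where
#'   masked).
#' @param mask length-4 logical availability; must be a prefix pattern
#'   (chi k available implies chi k-1 available).
#' @return length-4 numeric of conditioned errors; NA at masked positions.
#' @export
pre_torsion_errors <- function(e, mask) {
  if (length(e) != 4 || length(mask) != 4)
    stop_validation("e and mask must have length 4")
  if (any(diff(as.integer(mask)) > 0))
    stop_validation("mask must be a prefix pattern (chi k implies chi k-1)")
  if (any(mask & (!is.finite(e) | e < 0 | e > 2)))
    stop_validation("available errors must lie in [0, 2]")
  out <- rep(NA_real_, 4)
  if (!mask[1]) return(out)
  out[1] <- e[1]
  for (k in 2:4) {
    if (!mask[k]) break
    out[k] <- out[k - 1] + e[k] - out[k - 1] * e[k] / 2
  }
  out
}

#' Sequentially conditioned side-chain torsion-angle loss
#'
#' For each residue, per-chi chord errors are computed on the unit circle and
#' propagated through [pre_torsion_errors()]; the loss is the sum of the
#' chi1 errors and the conditioned chi2..chi4 errors over all residues that
#' possess each torsion, divided by the total residue count N (including
#' residues with no side-chain torsions).
#'
#' @param torsions_true,torsions_pred [torsion_set()] objects with identical
#'   masks.
#' @param symmetry_correct apply the pi-flip correction for flagged
#'   pi-periodic torsions before computing errors (default FALSE: the raw
#'   torsion difference is penalized).
#' @return scalar loss (non-negative).
#' @export
angle_loss <- function(torsions_true, torsions_pred, symmetry_correct = FALSE) {
  stopifnot(inherits(torsions_true, "torsion_set"),
            inherits(torsions_pred, "torsion_set"))
  check_same_masks(torsions_true, torsions_pred)
  n <- nrow(torsions_true$chi)
  total <- 0
  for (i in seq_len(n)) {
    m <- torsions_true$mask[i, ]
    if (!any(m)) next
    d <- chi_difference(torsions_true$chi[i, ], torsions_pred$chi[i, ],
                        torsions_true$symmetric[i, ], symmetry_correct)
    ct <- torsions_true$chi[i, ]
    e <- rep(NA_real_, 4)
    for (k in which(m))
      e[k] <- chi_error(angle_unit_vector(ct[k]),
                        angle_unit_vector(ct[k] + d[k]))
    tl <- pre_torsion_errors(e, m)
    total <- total + sum(tl[m])
  }
  total / n
}

#' FAPE configuration
#'
#' @param clamp clamping value in Angstrom applied to each per-pair error.
#' @param v inflection-point distance (Angstrom) of the pair-weight sigmoid.
#' @param h additive weight offset (dimensionless).
#' @param weighted whether [structure_losses()] applies distogram weighting.
#' @param normalize_by_weight_sum aggregate the weighted loss as
#'   sum(w * l) / sum(w) instead of the plain mean of weighted terms.
#' @param scale optional divisor applied to per-pair errors before clamping
#'   (default 1: the clamped error is reported in Angstrom).
#' @return an object of class `fape_config`.
#' @export
fape_config <- function(clamp = 10, v = 12.0, h = 1.5, weighted = TRUE,
                        normalize_by_weight_sum = FALSE, scale = 1) {
  if (clamp <= 0) stop_validation("clamp must be positive")
  if (h < 0) stop_validation("h must be non-negative")
  if (scale <= 0) stop_validation("scale must be positive")
  structure(list(clamp = clamp, v = v, h = h, weighted = weighted,
                 normalize_by_weight_sum = normalize_by_weight_sum,
                 scale = scale),
            class = "fape_config")
}

check_frames <- function(frames, what) {
  for (f in frames) if (!inherits(f, "rigid_frame"))
    stop_validation("%s must be a list of rigid_frame objects", what)
}

#' Frame-aligned point error
#'
#' Expresses every point in the local coordinates of every residue frame, for
#' prediction and truth, and reports the clamped Euclidean distance between
#' the two local positions for each (frame, point) pair. Invariant under any
#' common global rigid motion of a (frames, points) pair.
#'
#' @param frames_pred,frames_true lists of [rigid_frame()] of equal length.
#' @param points_pred,points_true m x 3 coordinate matrices of equal shape.
#' @param cfg a [fape_config()]; only `clamp` and `scale` are used here.
#' @return list with `pairs` (n_frames x m matrix of clamped per-pair errors,
#'   Angstrom) and `loss` (their unweighted mean).
#' @export
fape <- function(frames_pred, points_pred, frames_true, points_true,
                 cfg = fape_config()) {
  check_frames(frames_pred, "frames_pred"); check_frames(frames_true, "frames_true")
  points_pred <- as.matrix(points_pred); points_true <- as.matrix(points_true)
  if (length(frames_pred) != length(frames_true))
    stop_validation("prediction and truth have different frame counts")
  if (!all(dim(points_pred) == dim(points_true)))
    stop_validation("prediction and truth have different point counts")
  nf <- length(frames_pred)
  m <- nrow(points_pred)
  pairs <- matrix(NA_real_, nf, m)
  for (i in seq_len(nf)) {
    lp <- apply_rigid(rigid_invert(frames_pred[[i]]), points_pred)
    lt <- apply_rigid(rigid_invert(frames_true[[i]]), points_true)
    d <- lp - lt
    pairs[i, ] <- pmin(sqrt(rowSums(d * d)) / cfg$scale, cfg$clamp)
  }
  list(pairs = pairs, loss = mean(pairs))
}

#' Distogram-derived FAPE pair weight
#'
#' Sigmoid weight w = 1 / (1 + exp(-2 (v - d))) + h on the mode distance d of
#' a residue pair: strictly decreasing in d, ranging over (h, 1 + h), equal
#' to 0.5 + h at d = v. Larger weight is placed on residue pairs predicted to
#' be close.
#'
#' @param d distance(s) in Angstrom, non-negative.
#' @param cfg a [fape_config()] supplying `v` and `h`.
#' @return weight value(s).
#' @export
fape_weight <- function(d, cfg = fape_config()) {
  if (any(d < 0)) stop_validation("distances must be non-negative")
  1 / (1 + exp(-2 * (cfg$v - d))) + cfg$h
}

#' Distogram-weighted FAPE
#'
#' Multiplies each per-(frame, point) FAPE term by the sigmoid weight of the
#' mode Cbeta-Cbeta distance between the frame's residue and the residue
#' owning the point. By default the aggregate is the plain mean of the
#' weighted terms; with `cfg$normalize_by_weight_sum` it is the weighted
#' mean sum(w l) / sum(w). Self-pairs (i equal to the point's residue) use
#' the zero-distance weight, close to 1 + h.
#'
#' @inheritParams fape
#' @param point_residue integer vector mapping each point (row) to its owning
#'   residue position, 1-based.
#' @param mode_dist a [mode_distance_matrix()] (or plain symmetric matrix)
#'   of mode distances in Angstrom, indexed by residue position.
#' @return list with `pairs`, `weights` (both n_frames x m) and `loss`.
#' @export
weighted_fape <- function(frames_pred, points_pred, frames_true, points_true,
                          point_residue, mode_dist, cfg = fape_config()) {
  d <- if (inherits(mode_dist, "mode_distance_matrix")) mode_dist$d else as.matrix(mode_dist)
  base <- fape(frames_pred, points_pred, frames_true, points_true, cfg)
  m <- ncol(base$pairs)
  if (length(point_residue) != m)
    stop_validation("point_residue must map every point to a residue")
  if (any(point_residue < 1 | point_residue > nrow(d)))
    stop_validation("point_residue index outside the mode-distance matrix")
  if (nrow(d) < length(frames_pred))
    stop_validation("mode-distance matrix smaller than the frame count")
  w <- matrix(NA_real_, nrow(base$pairs), m)
  for (i in seq_len(nrow(w)))
    w[i, ] <- fape_weight(d[i, point_residue], cfg)
  wl <- w * base$pairs
  loss <- if (cfg$normalize_by_weight_sum) sum(wl) / sum(w) else mean(wl)
  list(pairs = base$pairs, weights = w, loss = loss)
}

#' 8-state secondary-structure cross-entropy loss
#'
#' Mean categorical cross-entropy between true DSSP 8-state labels and
#' predicted per-residue probability rows.
#'
#' @param true_labels character vector of single letters from
#'   {H, G, I, E, B, T, S, -}, or one string of length n.
#' @param pred_probs n x 8 matrix, each row a probability simplex (sum 1
#'   within 1e-6), columns in the alphabet order H, G, I, E, B, T, S, -.
#' @return scalar loss (non-negative); probabilities are floored at 1e-8
#'   before the log.
#' @export
secondary_structure_loss <- function(true_labels, pred_probs) {
  if (length(true_labels) == 1 && nchar(true_labels) > 1)
    true_labels <- strsplit(true_labels, "")[[1]]
  idx <- match(true_labels, SS8_ALPHABET)
  if (anyNA(idx))
    stop_validation("invalid secondary-structure label '%s' (allowed: %s)",
                    true_labels[which(is.na(idx))[1]],
                    paste(SS8_ALPHABET, collapse = ""))
  pred_probs <- as.matrix(pred_probs)
  if (nrow(pred_probs) != length(idx) || ncol(pred_probs) != 8)
    stop_validation("pred_probs must be n x 8 with n = number of labels")
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6))
    stop_validation("probability rows must sum to 1")
  p <- pred_probs[cbind(seq_along(idx), idx)]
  -mean(log(pmax(p, PROB_FLOOR)))
}

#' Per-residue side-chain confidence score
#'
#' s = 1 / (1 + (delta / delta0)^2) on the circular chi1 difference delta:
#' 1 for a perfect chi1, 0.5 at delta = delta0, decaying toward 0.
#'
#' @param delta chi1 difference(s) in radians; wrapped into (-pi, pi] before
#'   use.
#' @param delta0 reference angle difference in radians
#'   (default 12 degrees).
#' @return confidence value(s) in (0, 1].
#' @export
side_chain_confidence <- function(delta, delta0 = deg2rad(12)) {
  if (delta0 <= 0) stop_validation("delta0 must be positive")
  d <- wrap_angle(delta)
  1 / (1 + (d / delta0)^2)
}

#' Discretize a confidence score into uniform bins over [0, 1]
#'
#' Bins are half-open [lo, hi) except the last, which is closed so s = 1
#' falls in the final bin.
#'
#' @param s confidence value(s) in [0, 1].
#' @param n_bins number of uniform bins (default 50).
#' @return for scalar `s`, a list with `bin` (1-based index) and `onehot`
#'   (length `n_bins`); for vector `s`, a list with `bin` (integer vector)
#'   and `onehot` (matrix, one row per value).
#' @export
bin_confidence <- function(s, n_bins = 50) {
  if (any(!is.finite(s) | s < 0 | s > 1))
    stop_validation("confidence values must lie in [0, 1]")
  bin <- pmin(floor(s * n_bins), n_bins - 1) + 1L
  if (length(s) == 1) {
    onehot <- numeric(n_bins); onehot[bin] <- 1
  } else {
    onehot <- matrix(0, length(s), n_bins)
    onehot[cbind(seq_along(s), bin)] <- 1
  }
  list(bin = as.integer(bin), onehot = onehot)
}

#' Side-chain confidence cross-entropy loss
#'
#' One-hot cross-entropy between the binned true confidence scores and the
#' predicted bin probabilities, averaged over residues with an available
#' chi1.
#'
#' @param true_s per-residue true confidence values in [0, 1].
#' @param pred_probs n x n_bins probability matrix (rows sum to 1).
#' @param mask logical chi1 availability per residue (default: all TRUE).
#' @param n_bins number of bins (default 50; must match ncol(pred_probs)).
#' @return scalar loss.
#' @export
sc_confidence_loss <- function(true_s, pred_probs, mask = NULL, n_bins = 50) {
  pred_probs <- as.matrix(pred_probs)
  if (is.null(mask)) mask <- rep(TRUE, length(true_s))
  if (length(mask) != length(true_s) || nrow(pred_probs) != length(true_s))
    stop_validation("true_s, mask and pred_probs rows must align")
  if (ncol(pred_probs) != n_bins)
    stop_validation("pred_probs must have %d columns", n_bins)
  if (!any(mask))
    stop_validation("no residue with available chi1: loss undefined")
  if (any(abs(rowSums(pred_probs[mask, , drop = FALSE]) - 1) > 1e-6))
    stop_validation("probability rows must sum to 1")
  bins <- bin_confidence(true_s[mask], n_bins)$bin
  p <- pred_probs[mask, , drop = FALSE][cbind(seq_along(bins), bins)]
  -mean(log(pmax(p, PROB_FLOOR)))
}

#' Loss weights for the combined objective
#'
#' Weights c1..c4 scale the torsion-angle, weighted-FAPE, secondary-structure
#' and side-chain-confidence losses; `c_others` scales the six auxiliary
#' losses of the base prediction network (aux, distogram, MSA, confidence,
#' experimentally-resolved, violation), which this package accepts as
#' caller-supplied scalars. c1..c4 default to 1.0 each — library defaults,
#' not published values; `c_others` defaults to the published
#' (0.5, 0.3, 2.0, 0.01, 0.01, 1.0).
#'
#' @param c1,c2,c3,c4 non-negative weights.
#' @param c_others length-6 non-negative weight vector.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(c1 = 1, c2 = 1, c3 = 1, c4 = 1,
                         c_others = c(0.5, 0.3, 2.0, 0.01, 0.01, 1.0)) {
  w <- c(c1, c2, c3, c4, c_others)
  if (length(c_others) != 6) stop_validation("c_others must have length 6")
  if (any(!is.finite(w) | w < 0))
    stop_validation("loss weights must be finite and non-negative")
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c_others = c_others),
            class = "loss_weights")
}

#' Combined training objective
#'
#' L = c1 L_angle + c2 L_wfape + c3 L_secondary + c4 L_sc + c_others . L_others.
#' The six auxiliary losses enter as caller-supplied scalars and are never
#' computed here.
#'
#' @param l_angle,l_wfape,l_secondary,l_sc scalar component losses
#'   (non-negative).
#' @param l_others length-6 numeric of auxiliary loss values.
#' @param w a [loss_weights()].
#' @return the combined scalar loss.
#' @export
combined_loss <- function(l_angle, l_wfape, l_secondary, l_sc,
                          l_others = rep(0, 6), w = loss_weights()) {
  stopifnot(inherits(w, "loss_weights"))
  comp <- c(l_angle, l_wfape, l_secondary, l_sc, l_others)
  if (length(l_others) != 6) stop_validation("l_others must have length 6")
  if (any(!is.finite(comp)))
    stop_validation("all loss components must be finite")
  if (any(comp < 0))
    stop_validation("loss components must be non-negative")
  w$c1 * l_angle + w$c2 * l_wfape + w$c3 * l_secondary + w$c4 * l_sc +
    sum(w$c_others * l_others)
}
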