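# Assessment statistics: chi accuracy at a fixed degree criterion,
# per-sequence side-chain confidence, the contact-based template
# alignment-quality ratio, and CASP-style Z-score aggregation.

#' Pairwise alignment container
#'
#' Matched positions between a query and a template sequence, 1-based over
#' the ungapped sequences. Positions must be strictly increasing in both
#' columns (no crossing).
#'
#' @param pairs 2-column integer matrix (query_position, template_position);
#'   zero rows allowed (an empty alignment).
#' @param query_length,template_length ungapped sequence lengths.
#' @return an object of class `pair_alignment`.
#' @export
pair_alignment <- function(pairs, query_length, template_length) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0))
      stop_validation("alignment positions must be strictly increasing (no crossing)")
    if (any(pairs < 1) || any(pairs[, 1] > query_length) ||
        any(pairs[, 2] > template_length))
      stop_validation("alignment positions out of sequence bounds")
  }
  structure(list(pairs = pairs, query_length = as.integer(query_length),
                 template_length = as.integer(template_length)),
            class = "pair_alignment")
}

#' Chi-angle accuracy at a degree criterion
#'
#' The fraction of residues possessing chi(k) whose circular difference
#' between prediction and truth is strictly below the threshold. Flagged
#' pi-periodic torsions are corrected to the smaller of the two alternative
#' differences when `symmetry_correct` is on (the default for evaluation).
#'
#' @param torsions_true,torsions_pred [torsion_set()] objects with identical
#'   masks.
#' @param k which chi angle, 1..4.
#' @param threshold_deg correctness criterion in degrees (default 10).
#' @param symmetry_correct logical (default TRUE).
#' @return fraction in [0, 1].
#' @export
chi_accuracy <- function(torsions_true, torsions_pred, k = 1,
                         threshold_deg = 10, symmetry_correct = TRUE) {
  stopifnot(inherits(torsions_true, "torsion_set"),
            inherits(torsions_pred, "torsion_set"))
  check_same_masks(torsions_true, torsions_pred)
  if (!(k %in% 1:4)) stop_validation("k must be in 1..4")
  sel <- torsions_true$mask[, k]
  if (!any(sel))
    stop_undefined("no residue possesses chi%d: accuracy undefined", k)
  d <- chi_difference(torsions_true$chi[sel, k], torsions_pred$chi[sel, k],
                      torsions_true$symmetric[sel, k], symmetry_correct)
  mean(abs(d) < deg2rad(threshold_deg))
}

#' Per-sequence side-chain confidence
#'
#' The mean of the per-residue confidence scores
#' [side_chain_confidence()] over residues with an available chi1.
#'
#' @param torsions_true,torsions_pred [torsion_set()] objects with identical
#'   masks; at least one residue must possess chi1.
#' @param delta0 reference angle difference in radians (default 12 degrees).
#' @return mean confidence in (0, 1].
#' @export
sequence_confidence <- function(torsions_true, torsions_pred,
                                delta0 = deg2rad(12)) {
  stopifnot(inherits(torsions_true, "torsion_set"),
            inherits(torsions_pred, "torsion_set"))
  check_same_masks(torsions_true, torsions_pred)
  sel <- torsions_true$mask[, 1]
  if (!any(sel))
    stop_undefined("no residue possesses chi1: confidence undefined")
  d <- wrap_angle(torsions_pred$chi[sel, 1] - torsions_true$chi[sel, 1])
  mean(side_chain_confidence(d, delta0))
}

#' Template alignment-quality ratio
#'
#' Collects native residue pairs separated by more than `min_sep - 1`
#' positions in author numbering with Cbeta distance (CA fallback) below
#' `native_cutoff`. For each collected pair whose two residues are both
#' matched by the alignment, the template distance at the aligned positions
#' is compared with the native distance; the pair counts as similar when the
#' absolute difference is below `sim_threshold`. Pairs with either residue
#' unaligned count against the ratio, so short or poor alignments are
#' penalized. Returns similar / collected.
#'
#' @param native,template `structure_model` objects.
#' @param aln a [pair_alignment()] mapping native (query) positions to
#'   template positions.
#' @param min_sep minimum |i - j| in author numbering (default 4, i.e.
#'   separation greater than 3).
#' @param native_cutoff collect native pairs closer than this (Angstrom,
#'   default 8).
#' @param sim_threshold similarity criterion on the distance difference
#'   (Angstrom, default 3).
#' @return ratio in [0, 1].
#' @export
alignment_quality <- function(native, template, aln, min_sep = 4,
                              native_cutoff = 8, sim_threshold = 3) {
  stopifnot(inherits(native, "structure_model"),
            inherits(template, "structure_model"),
            inherits(aln, "pair_alignment"))
  nq <- length(native$residues)
  nt <- length(template$residues)
  if (aln$query_length != nq || aln$template_length != nt)
    stop_validation("alignment lengths do not match the structures (%d/%d vs %d/%d)",
                    aln$query_length, aln$template_length, nq, nt)
  cb_n <- cbeta_coords(native)
  cb_t <- cbeta_coords(template)
  if (anyNA(cb_n) || anyNA(cb_t))
    stop_validation("structures lack CB/CA for some residue")
  resno <- vapply(native$residues, function(r) r$index, 1L)
  dn <- as.matrix(stats::dist(cb_n))
  dt <- as.matrix(stats::dist(cb_t))
  map <- rep(NA_integer_, nq)
  if (nrow(aln$pairs)) map[aln$pairs[, 1]] <- aln$pairs[, 2]
  collected <- 0L
  similar <- 0L
  for (i in seq_len(nq - 1)) for (j in (i + 1):nq) {
    if (abs(resno[i] - resno[j]) < min_sep) next
    if (dn[i, j] >= native_cutoff) next
    collected <- collected + 1L
    ti <- map[i]; tj <- map[j]
    if (is.na(ti) || is.na(tj)) next
    if (abs(dn[i, j] - dt[ti, tj]) < sim_threshold) similar <- similar + 1L
  }
  if (collected == 0L)
    stop_undefined("no native pair satisfies the separation/distance filters")
  similar / collected
}

#' Metric table for Z-score aggregation
#'
#' Raw (group, domain, metric) values feeding the Z-score computation, with
#' a per-metric orientation flag. By default SCerror, Molprobity, BBerror and
#' DipDiff are lower-is-better; all other metrics are higher-is-better.
#'
#' @param rows data.frame with columns group, domain, metric, value.
#' @param higher_better optional named logical vector overriding or extending
#'   the default orientation per metric name.
#' @return an object of class `metric_table`.
#' @export
metric_table <- function(rows, higher_better = NULL) {
  need <- c("group", "domain", "metric", "value")
  if (!all(need %in% names(rows)))
    stop_validation("metric table needs columns %s", paste(need, collapse = ", "))
  rows <- rows[need]
  rows$value <- as.numeric(rows$value)
  if (any(!is.finite(rows$value)))
    stop_validation("metric values must be finite")
  key <- paste(rows$group, rows$domain, rows$metric, sep = "\r")
  if (anyDuplicated(key)) {
    d <- rows[duplicated(key), ][1, ]
    stop_validation("duplicate entry for (%s, %s, %s)", d$group, d$domain, d$metric)
  }
  lower <- c("SCerror", "Molprobity", "BBerror", "DipDiff")
  metrics <- unique(rows$metric)
  hb <- !(metrics %in% lower)
  names(hb) <- metrics
  if (!is.null(higher_better)) hb[names(higher_better)] <- higher_better
  structure(list(rows = rows, higher_better = hb), class = "metric_table")
}

#' Z-score configuration
#'
#' @param floor lowest retained Z (default -2); must be <= 0.
#' @param two_pass use the CASP-style two-pass procedure: standardize,
#'   discard first-pass outliers below -2, re-standardize over the remainder,
#'   then floor the final Z at `floor` (default TRUE).
#' @return an object of class `zscore_config`.
#' @export
zscore_config <- function(floor = -2, two_pass = TRUE) {
  if (floor > 0) stop_validation("floor must be <= 0")
  structure(list(floor = floor, two_pass = two_pass), class = "zscore_config")
}

#' Per-(domain, metric) Z-scores across groups
#'
#' For each (domain, metric), values are oriented so that higher is better
#' (lower-is-better metrics are negated), then standardized over groups with
#' the sample standard deviation. With `cfg$two_pass`, the mean and sd are
#' recomputed after excluding groups whose first-pass Z falls below -2, and
#' the final Z is floored at `cfg$floor`. A zero standard deviation yields
#' Z = 0 for every group.
#'
#' @param table a [metric_table()]; every (domain, metric) cell needs at
#'   least two groups.
#' @param cfg a [zscore_config()].
#' @return data.frame with columns group, domain, metric, z.
#' @export
z_scores <- function(table, cfg = zscore_config()) {
  stopifnot(inherits(table, "metric_table"))
  rows <- table$rows
  out <- NULL
  for (dm in split(rows, list(rows$domain, rows$metric), drop = TRUE)) {
    if (nrow(dm) < 2)
      stop_validation("(%s, %s) has a single group: Z-score undefined",
                      dm$domain[1], dm$metric[1])
    x <- dm$value
    if (!table$higher_better[[dm$metric[1]]]) x <- -x
    z <- standardize(x)
    if (cfg$two_pass) {
      keep <- z >= -2
      z <- if (sum(keep) >= 2) standardize_against(x, x[keep]) else z
      z <- pmax(z, cfg$floor)
    }
    out <- rbind(out, data.frame(group = dm$group, domain = dm$domain,
                                 metric = dm$metric, z = z))
  }
  rownames(out) <- NULL
  out
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

standardize_against <- function(x, ref) {
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(ref)) / s
}

ASSESSOR_METRICS <- list(
  third = c("GDT-HA", "reLLG", "ASE"),              # weight 1/6 each
  sixteenth = c("LDDT", "AA", "SG", "SCerror"),     # weight 1/16 each
  twelfth = c("Molprobity", "BBerror", "DipDiff")   # weight 1/12 each
)

#' Assessor sum-Z aggregation over domains
#'
#' Combines the ten per-metric Z-scores of one group into the assessor
#' score 1/6 (GDT-HA + reLLG + ASE) + 1/16 (LDDT + AA + SG + SCerror) +
#' 1/12 (Molprobity + BBerror + DipDiff) per domain, summed over domains.
#' The weights total exactly 1, so unit Z everywhere scores the domain
#' count. Domains missing any of the ten metrics are skipped with a warning.
#'
#' @param z data.frame with columns domain, metric, z for a single group
#'   (extra columns ignored). Metric names outside the eleven known assessor
#'   metrics raise a validation error (GDT-TS is accepted and ignored).
#' @return the scalar sum Z-score; attribute `n_domains` gives how many
#'   domains contributed.
#' @export
assessor_sum_z <- function(z) {
  need <- unlist(ASSESSOR_METRICS, use.names = FALSE)
  known <- c(need, "GDT-TS")
  bad <- setdiff(unique(z$metric), known)
  if (length(bad))
    stop_validation("unknown metric name(s): %s", paste(bad, collapse = ", "))
  z <- z[z$metric %in% need, , drop = FALSE]
  total <- 0
  used <- 0L
  for (dom in split(z, z$domain)) {
    have <- dom$metric
    if (!all(need %in% have)) {
      warning(sprintf("domain %s missing metrics %s: skipped", dom$domain[1],
                      paste(setdiff(need, have), collapse = ", ")))
      next
    }
    v <- structure(dom$z, names = dom$metric)
    total <- total + sum(v[ASSESSOR_METRICS$third]) / 6 +
      sum(v[ASSESSOR_METRICS$sixteenth]) / 16 +
      sum(v[ASSESSOR_METRICS$twelfth]) / 12
    used <- used + 1L
  }
  structure(total, n_domains = used)
}

#' Full CASP-style ranking from a metric table
#'
#' Convenience wrapper: computes [z_scores()] then [assessor_sum_z()] per
#' group and returns the ranking.
#'
#' @param table a [metric_table()].
#' @param cfg a [zscore_config()].
#' @return data.frame with columns group, sum_z, n_domains, sorted by
#'   decreasing sum_z.
#' @export
casp_ranking <- function(table, cfg = zscore_config()) {
  z <- z_scores(table, cfg)
  groups <- unique(z$group)
  sum_z <- numeric(length(groups))
  nd <- integer(length(groups))
  for (g in seq_along(groups)) {
    s <- assessor_sum_z(z[z$group == groups[g], , drop = FALSE])
    sum_z[g] <- as.numeric(s)
    nd[g] <- attr(s, "n_domains")
  }
  out <- data.frame(group = groups, sum_z = sum_z, n_domains = nd)
  out[order(-out$sum_z), , drop = FALSE]
}
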