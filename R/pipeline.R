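# Structure-level convenience layer: compare a model against its native
# structure and report every loss the package defines, honoring an optional
# YAML configuration.

#' Read a loss configuration file
#'
#' YAML key-value configuration with blocks `fape` (clamp, v, h, weighted,
#' normalize_by_weight_sum), `confidence` (delta0_deg, n_bins) and `weights`
#' (c1..c4, c_others). Missing keys fall back to package defaults.
#'
#' @param path YAML file path, or NULL for all defaults.
#' @return list with elements `fape` ([fape_config()]), `delta0` (radians),
#'   `n_bins`, `weights` ([loss_weights()]).
#' @export
read_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_format("no such file: %s", path)
    tryCatch(yaml::read_yaml(path),
             error = function(e) stop_format("cannot parse config %s: %s",
                                             path, conditionMessage(e)))
  }
  fp <- raw$fape
  conf <- raw$confidence
  wt <- raw$weights
  pick <- function(block, key, default)
    if (!is.null(block[[key]])) block[[key]] else default
  list(
    fape = fape_config(
      clamp = pick(fp, "clamp", 10),
      v = pick(fp, "v", 12.0),
      h = pick(fp, "h", 1.5),
      weighted = pick(fp, "weighted", TRUE),
      normalize_by_weight_sum = pick(fp, "normalize_by_weight_sum", FALSE)),
    delta0 = deg2rad(pick(conf, "delta0_deg", 12)),
    n_bins = pick(conf, "n_bins", 50),
    weights = loss_weights(
      c1 = pick(wt, "c1", 1), c2 = pick(wt, "c2", 1),
      c3 = pick(wt, "c3", 1), c4 = pick(wt, "c4", 1),
      c_others = pick(wt, "c_others", c(0.5, 0.3, 2.0, 0.01, 0.01, 1.0)))
  )
}

#' All structure-level losses of a model against its native
#'
#' Computes the torsion-angle loss, plain FAPE over the atoms shared
#' residue-by-residue between the two structures, the distogram-weighted
#' FAPE when a mode-distance source is supplied, the secondary-structure and
#' side-chain-confidence cross-entropies when their inputs are supplied, and
#' the combined objective over whatever components are available (absent
#' components enter as 0).
#'
#' @param native,model `structure_model` objects with equal residue counts
#'   and matching residue types.
#' @param mode_dist optional [mode_distance_matrix()] or [distogram()] (the
#'   mode matrix is extracted).
#' @param ss_true optional per-residue 8-state labels (see
#'   [secondary_structure_loss()]).
#' @param ss_probs optional n x 8 probability matrix.
#' @param sc_probs optional n x 50 (or `config$n_bins`) probability matrix
#'   for the side-chain-confidence loss; the true confidence is computed
#'   from the chi1 differences between native and model.
#' @param l_others length-6 auxiliary loss values (default zeros).
#' @param config a list from [read_config()] (default: package defaults).
#' @return list with components `l_angle`, `fape`, `l_wfape` (NA if no
#'   distogram), `l_secondary` (NA if no SS input), `l_sc` (NA if no
#'   confidence input), `combined`.
#' @export
structure_losses <- function(native, model, mode_dist = NULL, ss_true = NULL,
                             ss_probs = NULL, sc_probs = NULL,
                             l_others = rep(0, 6), config = read_config()) {
  stopifnot(inherits(native, "structure_model"),
            inherits(model, "structure_model"))
  if (length(native$residues) != length(model$residues))
    stop_validation("native and model have different residue counts")
  nm_n <- vapply(native$residues, function(r) r$name, "")
  nm_m <- vapply(model$residues, function(r) r$name, "")
  if (!identical(nm_n, nm_m))
    stop_validation("native and model residue types differ")
  cfg <- config$fape

  tt <- structure_torsions(native)
  tp <- structure_torsions(model)
  # availability can differ if either structure lacks atoms: intersect masks
  joint <- tt$mask & tp$mask
  tt2 <- torsion_set(ifelse(joint, tt$chi, NA), joint, tt$symmetric)
  tp2 <- torsion_set(ifelse(joint, tp$chi, NA), joint, tp$symmetric)
  l_angle <- angle_loss(tt2, tp2)

  fr_true <- backbone_frames(native)
  fr_pred <- backbone_frames(model)
  ok <- !vapply(fr_true, is.null, NA) & !vapply(fr_pred, is.null, NA)
  if (!any(ok)) stop_validation("no residue with a complete backbone frame")
  cp <- common_atom_points(model, native)
  fape_res <- fape(fr_pred[ok], cp$a, fr_true[ok], cp$b, cfg)

  l_wfape <- NA_real_
  if (!is.null(mode_dist)) {
    if (inherits(mode_dist, "distogram")) mode_dist <- mode_distance(mode_dist)
    l_wfape <- weighted_fape(fr_pred[ok], cp$a, fr_true[ok], cp$b,
                             cp$residue, mode_dist, cfg)$loss
  }

  l_secondary <- NA_real_
  if (!is.null(ss_true) && !is.null(ss_probs))
    l_secondary <- secondary_structure_loss(ss_true, ss_probs)

  l_sc <- NA_real_
  if (!is.null(sc_probs)) {
    sel <- joint[, 1]
    if (!any(sel)) stop_validation("no chi1 available for the confidence loss")
    delta <- wrap_angle(tp2$chi[, 1] - tt2$chi[, 1])
    true_s <- rep(0, length(sel))
    true_s[sel] <- side_chain_confidence(delta[sel], config$delta0)
    l_sc <- sc_confidence_loss(true_s, sc_probs, mask = sel,
                               n_bins = config$n_bins)
  }

  zero_if_na <- function(x) if (is.na(x)) 0 else x
  combined <- combined_loss(l_angle,
                            zero_if_na(l_wfape),
                            zero_if_na(l_secondary),
                            zero_if_na(l_sc),
                            l_others, config$weights)
  list(l_angle = l_angle, fape = fape_res$loss, l_wfape = l_wfape,
       l_secondary = l_secondary, l_sc = l_sc, combined = combined)
}
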