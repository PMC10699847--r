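test_that("angle unit vectors live on the unit circle", {
  expect_equal(angle_unit_vector(0), c(1, 0))
  expect_equal(angle_unit_vector(pi / 2), c(0, 1), tolerance = 1e-12)
  set.seed(21)
  v <- angle_unit_vector(runif(100, -pi, pi))
  expect_equal(sqrt(rowSums(v^2)), rep(1, 100), tolerance = 1e-12)
})

test_that("chi_error is the chord distance 2 sin(delta/2)", {
  expect_equal(chi_error(angle_unit_vector(1), angle_unit_vector(1)), 0)
  expect_equal(chi_error(angle_unit_vector(0), angle_unit_vector(pi)), 2)
  expect_equal(chi_error(angle_unit_vector(0), angle_unit_vector(pi / 2)),
               sqrt(2), tolerance = 1e-12)
  set.seed(22)
  a <- runif(200, -pi, pi); b <- runif(200, -pi, pi)
  d <- abs(((b - a + pi) %% (2 * pi)) - pi)
  expect_equal(chi_error(angle_unit_vector(a), angle_unit_vector(b)),
               2 * sin(d / 2), tolerance = 1e-12)
})

test_that("pre_torsion_errors follows the conditioning recursion", {
  all4 <- rep(TRUE, 4)
  expect_equal(pre_torsion_errors(rep(0, 4), all4), rep(0, 4))
  # a maximally wrong chi1 poisons every later torsion (absorbing fixed point)
  expect_equal(pre_torsion_errors(c(2, 0, 0, 0), all4), rep(2, 4))
  # a correct chi2 after an imperfect chi1 still carries the chi1 error
  out <- pre_torsion_errors(c(0.5, 0, NA, NA), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out, c(0.5, 0.5, NA, NA))
  expect_error(pre_torsion_errors(c(0.5, NA, 0.5, NA),
                                  c(TRUE, FALSE, TRUE, FALSE)),
               class = "foldeval_validation_error")
  expect_error(pre_torsion_errors(c(3, 0, 0, 0), all4),
               class = "foldeval_validation_error")
})

test_that("conditioned errors stay in [0,2], are monotone and dominate their inputs", {
  set.seed(23)
  n <- 5000
  a <- runif(n, 0, 2); b <- runif(n, 0, 2)
  f <- function(a, b) a + b - a * b / 2
  v <- f(a, b)
  expect_true(all(v >= 0 & v <= 2))
  expect_true(all(v >= pmax(a, b) - 1e-12))
  eps <- 1e-6
  expect_true(all(f(pmin(a + eps, 2), b) >= v - 1e-12))
  expect_true(all(f(a, pmin(b + eps, 2)) >= v - 1e-12))
})

test_that("angle_loss matches hand-computed cases", {
  mk <- function(chi, mask, sym = NULL) torsion_set(chi, mask, sym)
  # identical sets
  s <- make_peptide("SRLF", "helix", seed = 31)
  ts <- structure_torsions(s)
  expect_equal(angle_loss(ts, ts), 0)
  # single ARG with all four predictions pi off: every term saturates at 2
  chi_t <- matrix(c(0.3, -1, 2, 0.5), 1, 4)
  m <- matrix(TRUE, 1, 4)
  chi_p <- matrix(wrap_angle(chi_t + pi), 1, 4)
  expect_equal(angle_loss(mk(chi_t, m), mk(chi_p, m)), 8)
  # GLY (no chi) + SER with chi1 off by pi/2; N = 2
  chi_t <- rbind(rep(NA, 4), c(1, NA, NA, NA))
  m <- rbind(rep(FALSE, 4), c(TRUE, FALSE, FALSE, FALSE))
  chi_p <- rbind(rep(NA, 4), c(1 + pi / 2, NA, NA, NA))
  expect_equal(angle_loss(mk(chi_t, m), mk(chi_p, m)), sqrt(2) / 2)
  # mask mismatch
  expect_error(angle_loss(mk(chi_t, m),
                          mk(matrix(0, 2, 4), matrix(TRUE, 2, 4))),
               class = "foldeval_validation_error")
})

test_that("angle_loss symmetry correction only affects flagged torsions", {
  mk <- function(chi, mask, sym) torsion_set(chi, mask, sym)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)
  sym <- matrix(c(FALSE, TRUE, FALSE, FALSE), 1, 4)   # ASP-like terminal
  chi_t <- matrix(c(0.2, 0.7, NA, NA), 1, 4)
  chi_p <- matrix(c(0.2, wrap_angle(0.7 + pi), NA, NA), 1, 4)
  raw <- angle_loss(mk(chi_t, m, sym), mk(chi_p, m, sym))
  corrected <- angle_loss(mk(chi_t, m, sym), mk(chi_p, m, sym),
                          symmetry_correct = TRUE)
  expect_equal(raw, 2)        # chi2 pi off saturates
  expect_equal(corrected, 0)  # pi flip is equivalent under the flag
})

test_that("fape clamps per-pair errors and vanishes on perfect predictions", {
  s <- make_peptide("SRLFAG", "extended", seed = 41)
  fr <- backbone_frames(s)
  ap <- atom_points(s)
  self <- fape(fr, ap$points, fr, ap$points)
  expect_true(all(self$pairs == 0))
  expect_equal(self$loss, 0)
  # a 100 A displacement under an identity frame hits the clamp exactly
  id <- list(rigid_frame())
  r <- fape(id, matrix(c(100, 0, 0), 1), id, matrix(0, 1, 3))
  expect_equal(r$pairs[1, 1], 10)
  expect_equal(r$loss, 10)
  expect_error(fape(fr, ap$points, fr[-1], ap$points),
               class = "foldeval_validation_error")
})

test_that("fape is invariant under common global rigid motions", {
  s <- make_peptide("SRLFAGDE", "helix", seed = 42)
  fr <- backbone_frames(s)
  ap <- atom_points(s)
  model <- perturb_rigid(s, 2, seed = 43)
  frm <- backbone_frames(model)
  apm <- atom_points(model)
  base <- fape(frm, apm$points, fr, ap$points)$loss
  expect_gt(base, 0)
  set.seed(44)
  for (i in 1:20) {
    g <- random_rigid()
    fr_g <- lapply(frm, function(f) rigid_compose(g, f))
    pts_g <- apply_rigid(g, apm$points)
    expect_equal(fape(fr_g, pts_g, fr, ap$points)$loss, base,
                 tolerance = 1e-9)
  }
})

test_that("fape_weight has the documented sigmoid shape", {
  cfg <- fape_config()
  expect_equal(fape_weight(12.0, cfg), 2.0)
  expect_equal(fape_weight(1e4, cfg), 1.5)
  expect_equal(fape_weight(0, cfg), 1 / (1 + exp(-24)) + 1.5, tolerance = 1e-12)
  # strictly decreasing over the distances a distogram can express
  # (the sigmoid saturates to h in double precision far beyond that)
  d <- seq(0, 22, by = 0.25)
  w <- fape_weight(d, cfg)
  expect_true(all(diff(w) < 0))
  expect_true(all(w > cfg$h & w < 1 + cfg$h))
  expect_gte(min(fape_weight(seq(0, 100, 0.5), cfg)), cfg$h)
  expect_error(fape_weight(-1, cfg), class = "foldeval_validation_error")
})

test_that("weighted_fape reduces to known closed forms", {
  # clamp-saturated error with weight 2 at d = v gives 20 per pair
  id <- list(rigid_frame())
  r <- weighted_fape(id, matrix(c(100, 0, 0), 1), id, matrix(0, 1, 3),
                     point_residue = 1L,
                     mode_dist = mode_distance_matrix(matrix(0, 1, 1)),
                     cfg = fape_config())
  # self-pair at d = 0: weight ~ 1 + h
  expect_equal(r$weights[1, 1], fape_weight(0, fape_config()))
  # with d = v everywhere via a 2-residue system
  s <- make_peptide("SR", "helix", seed = 45)
  fr <- backbone_frames(s)
  ap <- atom_points(s)
  model <- perturb_rigid(s, 1.5, seed = 46)
  d <- matrix(12, 2, 2); diag(d) <- 0
  # h = 0.5 and d = v makes every off-diagonal weight exactly 1
  cfg1 <- fape_config(h = 0.5)
  wf <- weighted_fape(backbone_frames(model), atom_points(model)$points,
                      fr, ap$points, ap$residue,
                      mode_distance_matrix(d), cfg1)
  base <- fape(backbone_frames(model), atom_points(model)$points,
               fr, ap$points, cfg1)
  off <- outer(1:2, ap$residue, "!=")
  expect_equal(wf$pairs, base$pairs)
  expect_equal(wf$weights[off], rep(1, sum(off)))
  # perfect prediction stays 0 under any weighting
  wf0 <- weighted_fape(fr, ap$points, fr, ap$points, ap$residue,
                       mode_distance_matrix(d), fape_config())
  expect_equal(wf0$loss, 0)
  # weight-sum normalization with uniform weights equals the plain mean
  cfgn <- fape_config(h = 0.5, normalize_by_weight_sum = TRUE)
  dv <- matrix(12, 2, 2)  # d = v also on the diagonal: w = 1 everywhere
  wfn <- weighted_fape(backbone_frames(model), atom_points(model)$points,
                       fr, ap$points, ap$residue, dv, cfgn)
  expect_equal(wfn$loss, base$loss, tolerance = 1e-12)
})

test_that("secondary-structure loss matches cross-entropy closed forms", {
  labels <- c("H", "E", "-")
  onehot <- matrix(1e-30, 3, 8)
  onehot[cbind(1:3, c(1, 4, 8))] <- 1
  onehot <- onehot / rowSums(onehot)
  expect_lt(secondary_structure_loss(labels, onehot), 1e-7)
  uni <- matrix(1 / 8, 3, 8)
  expect_equal(secondary_structure_loss(labels, uni), log(8), tolerance = 1e-9)
  # one perfect + one uniform row averages to ln(8)/2
  mix <- rbind(onehot[1, ], rep(1 / 8, 8))
  expect_equal(secondary_structure_loss(c("H", "T"), mix), log(8) / 2,
               tolerance = 1e-7)
  expect_error(secondary_structure_loss("Z", matrix(1 / 8, 1, 8)),
               class = "foldeval_validation_error")
  expect_error(secondary_structure_loss("H", matrix(0.2, 1, 8)),
               class = "foldeval_validation_error")
  # a single string is accepted
  expect_equal(secondary_structure_loss("HE-", uni), log(8), tolerance = 1e-9)
})

test_that("side-chain confidence has the stated reference points", {
  d0 <- deg2rad(12)
  expect_equal(side_chain_confidence(0), 1)
  expect_equal(side_chain_confidence(d0), 0.5)
  expect_equal(side_chain_confidence(2 * d0), 0.2)
  expect_equal(side_chain_confidence(-d0), 0.5)   # even in delta
  d <- deg2rad(seq(0, 180, by = 5))
  expect_true(all(diff(side_chain_confidence(d)) < 0))
  # wraps circularly: a 350 degree difference is a 10 degree difference
  expect_equal(side_chain_confidence(deg2rad(350)),
               side_chain_confidence(deg2rad(-10)))
  expect_error(side_chain_confidence(0.1, delta0 = 0),
               class = "foldeval_validation_error")
})

test_that("confidence binning uses half-open bins with a closed last bin", {
  expect_equal(bin_confidence(0)$bin, 1L)
  expect_equal(bin_confidence(1)$bin, 50L)
  expect_equal(bin_confidence(0.5)$bin, 26L)  # floor(0.5 * 50) half-open
  expect_equal(bin_confidence(0.02 - 1e-12)$bin, 1L)
  expect_equal(bin_confidence(0.02)$bin, 2L)
  oh <- bin_confidence(c(0, 0.5, 1))$onehot
  expect_equal(dim(oh), c(3, 50))
  expect_equal(rowSums(oh), rep(1, 3))
  expect_equal(which(oh[2, ] == 1), 26L)
  expect_error(bin_confidence(1.2), class = "foldeval_validation_error")
})

test_that("side-chain confidence loss matches cross-entropy closed forms", {
  s_true <- c(0.1, 0.62, 0.99)
  bins <- bin_confidence(s_true)$bin
  perfect <- matrix(1e-30, 3, 50)
  perfect[cbind(1:3, bins)] <- 1
  perfect <- perfect / rowSums(perfect)
  expect_lt(sc_confidence_loss(s_true, perfect), 1e-7)
  uni <- matrix(1 / 50, 3, 50)
  expect_equal(sc_confidence_loss(s_true, uni), log(50), tolerance = 1e-9)
  # masked residues are excluded
  expect_equal(sc_confidence_loss(c(s_true, 0), rbind(uni, rep(0, 50)),
                                  mask = c(TRUE, TRUE, TRUE, FALSE)),
               log(50), tolerance = 1e-9)
  expect_error(sc_confidence_loss(c(0.5), matrix(1 / 50, 1, 50),
                                  mask = FALSE),
               class = "foldeval_validation_error")
})

test_that("combined loss is the stated weighted sum and linear in components", {
  expect_equal(combined_loss(0, 0, 0, 0), 0)
  # only the auxiliary losses, at their published default weights
  w0 <- loss_weights(c1 = 0, c2 = 0, c3 = 0, c4 = 0)
  expect_equal(combined_loss(1, 1, 1, 1, rep(1, 6), w0), 3.82)
  w1 <- loss_weights(c1 = 1, c2 = 0, c3 = 0, c4 = 0, c_others = rep(0, 6))
  expect_equal(combined_loss(8, 5, 5, 5, rep(9, 6), w1), 8)
  # linearity in each component
  w <- loss_weights(c1 = 0.5, c2 = 0.3, c3 = 2, c4 = 0.01)
  base <- combined_loss(1, 2, 3, 4, rep(0.5, 6), w)
  bump <- combined_loss(2, 2, 3, 4, rep(0.5, 6), w)
  expect_equal(bump - base, 0.5)
  expect_error(combined_loss(-1, 0, 0, 0), class = "foldeval_validation_error")
})
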