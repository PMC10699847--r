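test_that("chi accuracy counts circular differences under the degree criterion", {
  s <- make_peptide("SRLFKMEDQW", "helix", seed = 61)
  ts <- structure_torsions(s)
  expect_equal(chi_accuracy(ts, ts, k = 1), 1.0)
  # every chi1 off by 90 degrees
  chi_off <- ts$chi
  chi_off[ts$mask[, 1], 1] <- wrap_angle(chi_off[ts$mask[, 1], 1] + pi / 2)
  tp <- torsion_set(chi_off, ts$mask, ts$symmetric)
  expect_equal(chi_accuracy(ts, tp, k = 1), 0.0)
  # 3 of 10 within 10 degrees, 7 off by 20 degrees
  chi <- matrix(NA_real_, 10, 4); chi[, 1] <- seq(-2, 2, length.out = 10)
  m <- matrix(FALSE, 10, 4); m[, 1] <- TRUE
  off <- c(rep(deg2rad(5), 3), rep(deg2rad(20), 7))
  t_true <- torsion_set(chi, m)
  t_pred <- torsion_set(chi + cbind(off, NA, NA, NA) * m[, 1], m)
  expect_equal(chi_accuracy(t_true, t_pred, k = 1), 0.3)
  # undefined when no residue has the requested chi (no chi4 in SLF)
  short <- structure_torsions(make_peptide("SLF", "helix", seed = 1))
  expect_error(chi_accuracy(short, short, k = 4),
               class = "foldeval_undefined_error")
  expect_error(chi_accuracy(ts, ts, k = 7), class = "foldeval_validation_error")
})

test_that("chi accuracy respects the pi-symmetry flag and the 180-degree bound", {
  # ASP chi2 off by pi counts as correct only with symmetry correction
  chi_t <- matrix(c(0.4, 1.0, NA, NA), 1, 4)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 1, 4)
  sym <- matrix(c(FALSE, TRUE, FALSE, FALSE), 1, 4)
  t_true <- torsion_set(chi_t, m, sym)
  t_pred <- torsion_set(matrix(c(0.4, wrap_angle(1.0 + pi), NA, NA), 1, 4),
                        m, sym)
  expect_equal(chi_accuracy(t_true, t_pred, k = 2, symmetry_correct = TRUE), 1)
  expect_equal(chi_accuracy(t_true, t_pred, k = 2, symmetry_correct = FALSE), 0)
  # at threshold 180 any complete prediction is correct even without symmetry
  s <- make_peptide("SRLFKM", "extended", seed = 62)
  ts <- structure_torsions(s)
  tp <- structure_torsions(perturb_chi(s, 1e9, seed = 63))
  expect_equal(chi_accuracy(ts, tp, k = 1, threshold_deg = 180,
                            symmetry_correct = FALSE), 1.0)
})

test_that("sequence confidence averages the per-residue scores over chi1 residues", {
  s <- make_peptide("SRLFKM", "helix", seed = 64)
  ts <- structure_torsions(s)
  expect_equal(sequence_confidence(ts, ts), 1.0)
  d0 <- deg2rad(12)
  shift <- ts$chi
  shift[ts$mask[, 1], 1] <- wrap_angle(shift[ts$mask[, 1], 1] + d0)
  tp <- torsion_set(shift, ts$mask, ts$symmetric)
  expect_equal(sequence_confidence(ts, tp), 0.5)
  # half perfect, half off by delta0 -> 0.75
  half <- ts$chi
  idx <- which(ts$mask[, 1])
  half[idx[seq(1, length(idx), by = 2)], 1] <-
    wrap_angle(half[idx[seq(1, length(idx), by = 2)], 1] + d0)
  th <- torsion_set(half, ts$mask, ts$symmetric)
  expect_equal(sequence_confidence(ts, th), 0.75)
  # undefined with no chi1 anywhere
  g <- structure_torsions(make_peptide("GGG", "helix"))
  expect_error(sequence_confidence(g, g), class = "foldeval_undefined_error")
})

test_that("alignment quality is 1 on self-alignment and 0 with no matches", {
  s <- make_peptide(strrep("SRLFKMEDQW", 3), "helix", seed = 65)
  n <- length(s$residues)
  self <- pair_alignment(cbind(1:n, 1:n), n, n)
  expect_equal(alignment_quality(s, s, self), 1.0)
  empty <- pair_alignment(matrix(integer(), 0, 2), n, n)
  expect_equal(alignment_quality(s, s, empty), 0.0)
})

test_that("alignment quality matches the brute-force oracle on perturbed templates", {
  set.seed(66)
  s <- make_peptide(strrep("SRLFKMEDQW", 2), "helix", seed = 66)
  n <- length(s$residues)
  for (trial in 1:25) {
    templ <- perturb_rigid(s, runif(1, 0.5, 6), seed = 100 + trial)
    keep <- sort(sample(n, sample(5:n, 1)))
    aln <- pair_alignment(cbind(keep, keep), n, n)
    expect_equal(alignment_quality(s, templ, aln),
                 alignment_quality_oracle(s, templ, aln),
                 tolerance = 1e-12)
  }
})

test_that("alignment quality never increases as matched columns are removed", {
  s <- make_peptide(strrep("SRLFKMEDQW", 2), "helix", seed = 67)
  templ <- perturb_rigid(s, 2, seed = 68)
  n <- length(s$residues)
  cols <- 1:n
  prev <- Inf
  for (drop_to in c(n, 15, 10, 6)) {
    keep <- cols[seq_len(drop_to)]
    q <- alignment_quality(s, templ, pair_alignment(cbind(keep, keep), n, n))
    expect_lte(q, prev + 1e-12)
    prev <- q
  }
})

test_that("z-scores standardize per (domain, metric) with orientation", {
  tab <- metric_table(data.frame(
    group = rep(c("g1", "g2", "g3"), 2),
    domain = "d1",
    metric = rep(c("GDT-HA", "Molprobity"), each = 3),
    value = c(10, 20, 30, 10, 20, 30)))
  z1 <- z_scores(tab, zscore_config(two_pass = FALSE))
  zh <- z1$z[z1$metric == "GDT-HA"]
  zm <- z1$z[z1$metric == "Molprobity"]
  expect_equal(zh, c(-1, 0, 1))     # sample sd 10
  expect_equal(zm, c(1, 0, -1))     # lower-is-better flips orientation
  # one-pass z has mean 0, sd 1
  expect_equal(mean(zh), 0)
  expect_equal(sd(zh), 1)
  # equal values give all-zero z
  eq <- metric_table(data.frame(group = c("a", "b"), domain = "d",
                                metric = "LDDT", value = c(5, 5)))
  expect_equal(z_scores(eq)$z, c(0, 0))
  # single group is undefined
  one <- metric_table(data.frame(group = "a", domain = "d",
                                 metric = "LDDT", value = 1))
  expect_error(z_scores(one), class = "foldeval_validation_error")
})

test_that("two-pass z-scoring excludes low outliers and floors the result", {
  vals <- c(90:98, -500)   # one grossly poor group among ten
  tab <- metric_table(data.frame(group = paste0("g", 1:10), domain = "d",
                                 metric = "GDT-HA", value = vals))
  z2 <- z_scores(tab, zscore_config(floor = -2, two_pass = TRUE))$z
  z1 <- z_scores(tab, zscore_config(two_pass = FALSE))$z
  # the outlier falls below -2 in the first pass and is floored in the second
  expect_lt(z1[10], -2)
  expect_equal(z2[10], -2)
  # remaining groups standardized against the clean subset
  expect_equal(z2[1:9], (vals[1:9] - mean(vals[1:9])) / sd(vals[1:9]))
})

test_that("assessor sum-Z weights total one and add over domains", {
  metrics <- c("GDT-HA", "reLLG", "ASE", "LDDT", "AA", "SG", "SCerror",
               "Molprobity", "BBerror", "DipDiff")
  z1 <- data.frame(domain = "d1", metric = metrics, z = 1)
  expect_equal(as.numeric(assessor_sum_z(z1)), 1.0)
  z0 <- data.frame(domain = "d1", metric = metrics, z = 0)
  expect_equal(as.numeric(assessor_sum_z(z0)), 0)
  z2 <- rbind(z1, transform(z1, domain = "d2"))
  expect_equal(as.numeric(assessor_sum_z(z2)), 2.0)
  expect_equal(attr(assessor_sum_z(z2), "n_domains"), 2L)
  # the group weighting: 1/6 on the first block, 1/16 second, 1/12 third
  zx <- data.frame(domain = "d1", metric = metrics,
                   z = c(6, 0, 0, 16, 0, 0, 0, 12, 0, 0))
  expect_equal(as.numeric(assessor_sum_z(zx)), 3)
  expect_error(assessor_sum_z(data.frame(domain = "d", metric = "TM", z = 1)),
               class = "foldeval_validation_error")
  # a domain missing metrics is skipped with a warning
  expect_warning(res <- assessor_sum_z(rbind(z1, data.frame(
    domain = "d3", metric = "LDDT", z = 5))), "skipped")
  expect_equal(as.numeric(res), 1.0)
})

test_that("casp_ranking orders groups by sum-Z", {
  metrics <- c("GDT-HA", "reLLG", "ASE", "LDDT", "AA", "SG", "SCerror",
               "Molprobity", "BBerror", "DipDiff")
  rows <- expand.grid(group = c("good", "mid", "poor"), domain = c("d1", "d2"),
                      metric = metrics, stringsAsFactors = FALSE)
  base <- c(good = 30, mid = 20, poor = 10)
  rows$value <- base[rows$group]
  lower <- rows$metric %in% c("SCerror", "Molprobity", "BBerror", "DipDiff")
  rows$value[lower] <- 40 - rows$value[lower]  # lower-better: invert raw scale
  rk <- casp_ranking(metric_table(rows), zscore_config(two_pass = FALSE))
  expect_equal(rk$group, c("good", "mid", "poor"))
  expect_equal(rk$sum_z, c(2, 0, -2))
  expect_equal(rk$n_domains, c(2L, 2L, 2L))
})
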