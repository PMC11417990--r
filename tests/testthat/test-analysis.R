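test_that("radius of gyration matches hand-computed geometries", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(10, 0, 0))), 5)
  collinear <- cbind(c(0, 3.8, 7.6), 0, 0)
  expect_equal(radius_of_gyration(collinear), sqrt(2 * 3.8^2 / 3),
               tolerance = 1e-12)
  expect_equal(radius_of_gyration(collinear), 3.103, tolerance = 1e-3)
})

test_that("ensemble Rg pooling and replicate errors follow the stated rule", {
  mk <- function(rgs, rep) {
    # beads on the x axis, dimer separation 2 * rg
    frames <- array(0, c(2, 3, length(rgs)))
    frames[1, 1, ] <- -rgs
    frames[2, 1, ] <- rgs
    fake_trajectory(frames, steps = seq_along(rgs) * 100, replicate = rep)
  }
  const <- mk(rep(13.5, 10), 1)
  s1 <- summarize_rg(const)
  expect_equal(s1$mean_rg, 13.5)
  expect_true(is.na(s1$rg_sd))

  two <- structure(list(mk(rep(10, 5), 1), mk(rep(12, 5), 2)),
                   class = "cg_ensemble")
  s2 <- summarize_rg(two)
  expect_equal(s2$mean_rg, 11)
  expect_equal(s2$rg_sd, sqrt(2))
  expect_equal(s2$n_replicates, 2)

  # equilibration removes exactly the step-index prefix
  s3 <- summarize_rg(mk(c(100, 100, 13, 13), 1), equilibration_steps = 200)
  expect_equal(s3$mean_rg, 13)
  expect_equal(s3$n_frames, 2)
  expect_error(summarize_rg(mk(c(1, 2), 1), equilibration_steps = 1e6),
               "no frames")
})

test_that("delta Rg follows its defining ratio and sign convention", {
  expect_equal(delta_rg(15, 10), 50)
  expect_equal(delta_rg(10, 10), 0)
  expect_equal(delta_rg(12, 16), -25)
  expect_error(delta_rg(10, 0), "non-zero")
})

test_that("contact probabilities threshold distances and count frames", {
  frames <- array(0, c(6, 3, 2))
  frames[, 1, 1] <- c(0, 3.8, 7.6, 11.4, 15.2, 9.9)   # bead 6 at 9.9 of bead 1
  frames[6, 2, 1] <- 0
  frames[, 1, 2] <- c(0, 3.8, 7.6, 11.4, 15.2, 30)    # bead 6 far away
  tr <- fake_trajectory(frames)
  cm <- contact_map(tr, cutoff = 10)
  expect_equal(cm$p[1, 6], 0.5)   # contact in one of two frames
  expect_equal(cm$p[6, 1], 0.5)
  expect_equal(cm$p[1, 5], 0)     # 15.2 A > 10 A in both frames
  expect_true(all(is.na(cm$p[abs(row(cm$p) - col(cm$p)) <= 3])))
  single <- contact_map(fake_trajectory(frames[, , 1, drop = FALSE]),
                        cutoff = 10)
  expect_equal(single$p[1, 6], 1)
  expect_equal(contact_map(fake_trajectory(frames[, , 2, drop = FALSE]),
                           cutoff = 10)$p[1, 6], 0)
})

test_that("simulated contact maps are symmetric, bounded and masked", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 5e4, output_every = 500, seed = 12)
  cm <- contact_map(tr, cutoff = 10, equilibration_steps = 1e4)
  off <- cm$p[!is.na(cm$p)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(cm$p, t(cm$p))
  expect_true(all(is.na(diag(cm$p))))
  td <- tidy(cm)
  expect_true(all(td$j > td$i + 3))
})

test_that("contact map differences are antisymmetric and class filters work", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  a <- contact_map(simulate_chain(top, ff, n_steps = 2e4, output_every = 500,
                                  seed = 1))
  b <- contact_map(simulate_chain(top, ff, n_steps = 2e4, output_every = 500,
                                  seed = 2))
  dab <- contact_map_difference(a, b)
  dba <- contact_map_difference(b, a)
  expect_equal(dab$p, -dba$p)
  zero <- contact_map_difference(a, a)
  expect_true(all(zero$p[!is.na(zero$p)] == 0))

  cc <- contact_correlation(a, b)
  expect_equal(nrow(cc), sum(upper.tri(a$p) & !is.na(a$p)))
  ar <- contact_correlation(a, b, classes = c("aromatic", "cationic", "his"))
  cls <- residue_classes(top$codes)
  ok <- cls$class %in% c("aromatic", "cationic") | cls$is_his
  expect_true(all(ok[ar$i] & ok[ar$j]))
  expect_gt(nrow(ar), 0)
})

test_that("residue classes mirror the aromatic/cationic/anionic scheme", {
  cl <- residue_classes(c("F", "Y", "W", "H0", "K", "R", "H+", "D", "E", "S", "H"))
  expect_equal(cl$class[1:4], rep("aromatic", 4))
  expect_equal(cl$class[5:7], rep("cationic", 3))
  expect_equal(cl$class[8:9], rep("anionic", 2))
  expect_equal(cl$class[10:11], c("other", "other"))
  expect_equal(which(cl$is_his), c(4, 7, 11))
})

test_that("pair-class energetics: absent classes, single pairs, controls", {
  ff <- get_ff("high_pH", salt_mM = 120)
  # no His at all: His-His class is absent, not zero
  top_nohis <- build_chain(assign_protonation("KADWGAYSKA", "high_pH"), ff)
  tr <- simulate_chain(top_nohis, ff, n_steps = 2000, output_every = 500,
                       seed = 3)
  pe <- mean_pair_energy(tr, top_nohis, ff)
  expect_false("His-His" %in% pe$pair_class)

  # a single His-Arg pair in a frozen frame equals the lj1012 value, SD 0
  top2 <- build_chain(assign_protonation("HAAAR", "high_pH"), ff)
  x <- initial_conformation(top2, method = "extended")
  frames <- array(rep(x, 2), c(5, 3, 2))
  tr2 <- fake_trajectory(frames, codes = top2$codes)
  pe2 <- mean_pair_energy(tr2, top2, ff)
  row <- pe2[pe2$pair_class == "His-Arg", ]
  expect_equal(row$n_pairs, 1)
  expect_equal(row$sd_energy, 0)
  expect_equal(row$mean_energy,
               lj1012(4 * 3.8, ff$epsilon["H0", "R"], ff$sigma["H0", "R"]))

  # control parameters make the His0-His0 class exactly zero
  ctl <- get_ff("control_high", salt_mM = 120)
  top3 <- build_chain(assign_protonation("HAAAH", "control_high"), ctl)
  tr3 <- fake_trajectory(array(rep(initial_conformation(top3, method = "extended"), 3),
                               c(5, 3, 3)), codes = top3$codes)
  pe3 <- mean_pair_energy(tr3, top3, ctl)
  expect_equal(pe3$mean_energy[pe3$pair_class == "His-His"], 0)
})

test_that("MSE and chi-squared follow their formulas and properties", {
  expect_equal(rg_mse(c(14, 12), c(13, 13)), 1.0)
  expect_equal(rg_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(rg_mse(1:3, 1:4), "length")
  expect_equal(rg_chi2(c(14, 12), c(13, 13), c(0.5, 1)), 4 + 1)
  expect_error(rg_chi2(1, 2, 0), "positive")

  withr::with_seed(7, {
    comp <- rnorm(10, 20, 3)
    expt <- rnorm(10, 20, 3)
    err <- runif(10, 0.5, 2)
    expect_equal(rg_mse(comp, expt), sum((comp - expt)^2) / 10,
                 tolerance = 1e-12)
    expect_equal(rg_chi2(comp, expt, err), sum(((comp - expt) / err)^2),
                 tolerance = 1e-12)
    # chi2 with unit errors reduces to n * MSE
    expect_equal(rg_chi2(comp, expt), 10 * rg_mse(comp, expt))
    # permutation covariance
    perm <- sample(10)
    expect_equal(rg_mse(comp[perm], expt[perm]), rg_mse(comp, expt))
    # translation sensitivity: shifting computed by c changes MSE by c^2
    # when the residuals are centered
    resid <- comp - expt
    comp0 <- expt + resid - mean(resid)
    expect_equal(rg_mse(comp0 + 2, expt), rg_mse(comp0, expt) + 4,
                 tolerance = 1e-10)
  })
})

test_that("score tables expose per-sequence and summary views", {
  d <- data.frame(name = c("a", "b"), computed = c(14, 12),
                  experimental = c(13, 13), error = c(1, 1))
  sc <- score_rg(d)
  expect_equal(sc$mse, 1)
  expect_equal(glance(sc)$chi2, 2)
  expect_equal(tidy(sc)$residual, c(1, -1))
})

test_that("Flory reference sizes and normalized distributions", {
  expect_equal(flory_rg(1), 2.54)
  expect_equal(flory_rg(24), 13.26, tolerance = 1e-3)
  expect_equal(flory_rg(448), 60.8, tolerance = 1e-3)
  withr::with_seed(5, {
    rg <- rnorm(500, 10, 1)
    h <- normalized_rg_distribution(rg, 24)
    expect_true(all(h$count >= 0))
    expect_equal(sum(h$count), 500)
    # peak near 10 / 13.26
    expect_equal(h$ratio_mid[which.max(h$count)], 10 / flory_rg(24),
                 tolerance = 0.05)
  })
})

test_that("autoplot methods return ggplot objects", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 5000, output_every = 500, seed = 2)
  cm <- contact_map(tr)
  expect_s3_class(autoplot(cm), "ggplot")
  sc <- score_rg(data.frame(name = "x", computed = 14, experimental = 13))
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(plot_rg_distribution(tr, n_residues = 24), "ggplot")
})
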