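test_that("LJ 10-12 closed-form values and limits", {
  expect_equal(lj1012(6, 0.5, 6), -0.5)          # minimum depth -eps at sigma
  expect_lt(abs(lj1012(60, 1, 6)), 1e-9)         # decay to zero
  expect_equal(lj1012(0.9 * 6, 0.5, 6), 0.2479, tolerance = 1e-3)
  expect_error(lj1012(0, 1, 6), "singular")
})

test_that("LJ 10-12 minimum sits at sigma with depth -eps for every pair", {
  ff <- get_ff("high_pH")
  codes <- ff$residues$code
  for (a in codes) {
    for (b in codes) {
      eps <- ff$epsilon[a, b]
      sig <- ff$sigma[a, b]
      if (eps == 0) next
      expect_equal(lj1012(sig, eps, sig), -eps)
      # derivative vanishes at sigma; curvature positive
      h <- 1e-6
      expect_lt(abs(lj1012(sig + h, eps, sig) - lj1012(sig - h, eps, sig)) /
                  (2 * h), 1e-6 * eps)
      expect_gt(lj1012(sig * 0.99, eps, sig), -eps)
      expect_gt(lj1012(sig * 1.01, eps, sig), -eps)
    }
  }
})

test_that("Debye-Hueckel pair energy matches the closed form and its signs", {
  ff <- get_ff("high_pH")
  el <- ff$electrostatics
  el$kappa <- 0
  # 332 / (80 * 4.15) = 1.00 kcal/mol before unit conversion
  expect_equal(debye_huckel(1, 1, 4.15, el, convert = FALSE), 1.0,
               tolerance = 1e-4)
  expect_lt(debye_huckel(1, -1, 7, el), 0)
  expect_equal(debye_huckel(0, 1, 7, el), 0)
  expect_error(debye_huckel(1, 1, 0, el), "singular")
  # magnitude decreasing in r and in kappa
  el2 <- ff$electrostatics
  r <- seq(3, 30, by = 0.5)
  expect_true(all(diff(debye_huckel(1, 1, r, el2)) < 0))
  el3 <- el2; el3$kappa <- el2$kappa * 3
  expect_true(all(debye_huckel(1, 1, r, el3) < debye_huckel(1, 1, r, el2)))
})

test_that("short chains have no nonbonded pairs inside the exclusion", {
  ff <- get_ff("high_pH")
  top4 <- build_chain(assign_protonation("KKKK", "high_pH"), ff)
  x4 <- initial_conformation(top4, method = "extended")
  e4 <- chain_energy(x4, top4, ff, cutoffs = FALSE)
  expect_equal(e4$contacts, 0)
  expect_equal(e4$electrostatic, 0)

  top5 <- build_chain(assign_protonation("KAAAK", "high_pH"), ff)
  x5 <- initial_conformation(top5, method = "extended")
  e5 <- chain_energy(x5, top5, ff, cutoffs = FALSE)
  r15 <- 4 * 3.8
  expect_equal(e5$contacts,
               lj1012(r15, ff$epsilon["K", "K"], ff$sigma["K", "K"]))
  expect_equal(e5$electrostatic,
               debye_huckel(1, 1, r15, ff$electrostatics))
})

test_that("vectorized energies equal the brute-force oracle on random frames", {
  ff <- get_ff("low_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "low_pH"), ff)
  withr::with_seed(31, {
    for (k in 1:5) {
      x <- initial_conformation(top, seed = k, method = "random_walk")
      fast <- chain_energy(x, top, ff, cutoffs = FALSE)
      ref <- reference_energy(x, top, ff)
      for (term in names(fast)) {
        expect_equal(fast[[term]], ref[[term]],
                     tolerance = 1e-10, label = term)
      }
    }
  })
})

test_that("the breakdown total equals the sum of components", {
  fx <- relaxed_frame("AGPHKRDWPYEAGHSK", "low_pH")
  e <- chain_energy(fx$coords, fx$topology, fx$forcefield)
  expect_equal(e$total,
               e$bonded + e$angular + e$dihedral + e$contacts + e$electrostatic,
               tolerance = 1e-12)
  expect_gt(e$dihedral, 0)  # proline present
})

test_that("analytic forces match finite differences on relaxed frames", {
  fx <- relaxed_frame("AGPHKRDWPYEAGHSK", "low_pH", seed = 8)
  f <- chain_forces(fx$coords, fx$topology, fx$forcefield, cutoffs = FALSE)
  num <- numerical_forces(fx$coords, fx$topology, fx$forcefield)
  scale <- max(abs(f))
  expect_lt(max(abs(f - num)) / scale, 1e-5)
  expect_lt(max(abs(colSums(f))), 1e-9)  # Newton's third law
})

test_that("energy is invariant under rigid translation and rotation", {
  fx <- relaxed_frame(hst5_sequence(), "high_pH", seed = 4)
  e0 <- chain_energy(fx$coords, fx$topology, fx$forcefield)$total
  shifted <- sweep(fx$coords, 2, c(11.3, -5.2, 100))
  expect_equal(chain_energy(shifted, fx$topology, fx$forcefield)$total, e0,
               tolerance = 1e-9)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- fx$coords %*% rot
  expect_equal(chain_energy(rotated, fx$topology, fx$forcefield)$total, e0,
               tolerance = 1e-9)
})

test_that("zeroed parameters give zero energy and forces", {
  ff <- get_ff("high_pH")
  ff$epsilon[] <- 0
  ff <- set_ionic_strength(ff, 0.15)
  top <- build_chain(assign_protonation("GSGSGSGS", "high_pH"), ff)
  # planar zigzag at the equilibrium bond length and bond angle
  th0 <- ff$bonded$theta0
  turn <- (pi - th0) / 2
  dirs <- ifelse(seq_len(top$n - 1) %% 2 == 0, -turn, turn)
  x <- matrix(0, top$n, 3)
  for (i in 2:top$n) {
    x[i, ] <- x[i - 1, ] + 3.8 * c(cos(dirs[i - 1]), sin(dirs[i - 1]), 0)
  }
  e <- chain_energy(x, top, ff, cutoffs = FALSE)
  expect_equal(e$total, 0, tolerance = 1e-12)
  expect_equal(max(abs(chain_forces(x, top, ff))), 0, tolerance = 1e-9)
})

test_that("neutral sequences have exactly zero electrostatic energy", {
  ff <- get_ff("high_pH")
  top <- build_chain(assign_protonation("SSSSSSSSSS", "high_pH"), ff)
  x <- initial_conformation(top, seed = 3, method = "random_walk")
  expect_equal(chain_energy(x, top, ff, cutoffs = FALSE)$electrostatic, 0)
})

test_that("salt screening weakens the electrostic energy of Hst5", {
  typed <- assign_protonation(hst5_sequence(), "low_pH")
  ff120 <- get_ff("low_pH", salt_mM = 120)
  ff0 <- set_ionic_strength(ff120, 0)
  top <- build_chain(typed, ff120)
  x <- initial_conformation(top, seed = 6, method = "random_walk")
  e120 <- chain_energy(x, top, ff120, cutoffs = FALSE)$electrostatic
  e0 <- chain_energy(x, top, ff0, cutoffs = FALSE)$electrostatic
  expect_lt(abs(e120), abs(e0))
})

test_that("control parameters change only His0-His0 and His0-Arg contacts", {
  # low-pH chain has no His0: identical contact energies
  ff <- get_ff("high_pH", salt_mM = 120)
  ctl <- get_ff("control_high", salt_mM = 120)
  typed_low <- assign_protonation(hst5_sequence(), "low_pH")
  top_low <- build_chain(typed_low, ff)
  x <- initial_conformation(top_low, seed = 13, method = "random_walk")
  expect_equal(chain_energy(x, top_low, ctl, cutoffs = FALSE)$contacts,
               chain_energy(x, top_low, ff, cutoffs = FALSE)$contacts)
  # high-pH chain: difference equals the summed His0-His0/His0-Arg terms
  typed_high <- assign_protonation(hst5_sequence(), "high_pH")
  top_high <- build_chain(typed_high, ff)
  e_full <- chain_energy(x, top_high, ff, cutoffs = FALSE)$contacts
  e_ctl <- chain_energy(x, top_high, ctl, cutoffs = FALSE)$contacts
  manual <- 0
  for (i in 1:(top_high$n - 1)) {
    for (j in (i + 1):top_high$n) {
      if (j - i <= 3) next
      pair <- sort(c(top_high$codes[i], top_high$codes[j]))
      if (identical(pair, c("H0", "H0")) || identical(pair, c("H0", "R"))) {
        r <- sqrt(sum((x[i, ] - x[j, ])^2))
        manual <- manual + lj1012(r, ff$epsilon[pair[1], pair[2]],
                                  ff$sigma[pair[1], pair[2]])
      }
    }
  }
  expect_equal(e_full - e_ctl, manual, tolerance = 1e-10)
})
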