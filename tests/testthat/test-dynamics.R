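test_that("identical seeds give bit-identical trajectories", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  a <- simulate_chain(top, ff, n_steps = 5000, output_every = 500, seed = 42)
  b <- simulate_chain(top, ff, n_steps = 5000, output_every = 500, seed = 42)
  expect_identical(a$frames, b$frames)
  expect_identical(a$coords, b$coords)
  c <- simulate_chain(top, ff, n_steps = 5000, output_every = 500, seed = 43)
  expect_false(identical(a$coords, c$coords))
})

test_that("frame count and bookkeeping follow the output stride", {
  ff <- get_ff("high_pH")
  top <- build_chain(assign_protonation("AAAAAA", "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 10000, output_every = 250, seed = 1)
  expect_equal(dim(tr$frames), c(6, 3, 40))
  expect_equal(tr$steps, seq(250, 10000, by = 250))
  expect_true(all(is.finite(tr$frames)))
  expect_error(simulate_chain(top, ff, n_steps = 100, dt = -1), "positive")
})

test_that("zero-friction velocity Verlet conserves total energy", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation("GSKHDYAGSA", "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 1e5, dt = 0.002, friction = 0,
                       output_every = 1000, seed = 17)
  pot <- vapply(seq_len(dim(tr$frames)[3]), function(f) {
    chain_energy(tr$frames[, , f], top, ff)$total
  }, numeric(1))
  etot <- pot + tr$kinetic
  drift <- (max(etot) - min(etot)) / abs(mean(etot))
  expect_lt(drift, 1e-4)
})

test_that("a thermostatted harmonic dimer satisfies equipartition", {
  ff <- get_ff("high_pH")
  top <- build_chain(assign_protonation("AA", "high_pH"), ff)
  kT <- 0.45
  tr <- simulate_chain(top, ff, n_steps = 6e5, dt = 0.005, friction = 0.5,
                       temperature = kT, output_every = 50, seed = 23)
  d <- sqrt(colSums((tr$frames[1, , ] - tr$frames[2, , ])^2))
  # bond potential k (d - d0)^2 with k = 20: var(d) = kT / (2 k)
  expect_equal(var(d), kT / (2 * 20), tolerance = 0.05)
})

test_that("sampled kinetic temperature converges to the set point", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 2e5, friction = 0.2,
                       output_every = 200, seed = 3)
  kin_T <- mean(tr$kinetic[-(1:100)]) / (1.5 * top$n)
  expect_equal(kin_T, 0.45, tolerance = 0.05)
})

test_that("with noise off and zero initial momentum the COM is pinned", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  tr <- simulate_chain(top, ff, n_steps = 20000, temperature = 0,
                       friction = 0.5, output_every = 1000, seed = 2,
                       init = "random_walk")
  com0 <- colMeans(tr$frames[, , 1])
  comN <- colMeans(tr$frames[, , dim(tr$frames)[3]])
  expect_equal(comN, com0, tolerance = 1e-8)
})

test_that("damped zero-temperature dynamics relaxes the energy", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  x0 <- initial_conformation(top, seed = 19, method = "random_walk")
  tr <- simulate_chain(top, ff, n_steps = 50000, temperature = 0,
                       friction = 5, dt = 0.005, output_every = 5000,
                       seed = 2, init = x0)
  pot <- vapply(seq_len(dim(tr$frames)[3]), function(f) {
    chain_energy(tr$frames[, , f], top, ff)$total
  }, numeric(1))
  e0 <- chain_energy(x0, top, ff)$total
  expect_true(all(diff(c(e0, pot)) < 1e-6))
  expect_lt(pot[length(pot)], e0)
})

test_that("replicates use distinct seeds and reduce to a single run", {
  ff <- get_ff("high_pH", salt_mM = 120)
  top <- build_chain(assign_protonation(hst5_sequence(), "high_pH"), ff)
  ens <- run_replicates(top, ff, n_replicates = 3, base_seed = 7,
                        n_steps = 3000, output_every = 500)
  expect_length(ens, 3)
  seeds <- vapply(ens, function(t) t$settings$seed, numeric(1))
  expect_equal(seeds, c(8, 9, 10))
  expect_false(identical(ens[[1]]$coords, ens[[2]]$coords))
  one <- run_replicates(top, ff, n_replicates = 1, base_seed = 7,
                        n_steps = 3000, output_every = 500)
  expect_identical(one[[1]]$frames,
                   simulate_chain(top, ff, seed = 8, n_steps = 3000,
                                  output_every = 500)$frames)
})

test_that("an ideal chain's size grows with length, insensitive to seed", {
  ff <- get_ff("high_pH")
  ff$epsilon[] <- 0
  kT <- 0.45
  rg_of <- function(seq, seed) {
    top <- build_chain(assign_protonation(seq, "high_pH"), ff)
    tr <- simulate_chain(top, ff, n_steps = 4e5, friction = 0.2,
                         output_every = 400, seed = seed)
    mean(rg_series(tr, equilibration_steps = 8e4)$rg)
  }
  r10a <- rg_of(strrep("G", 10), 1)
  r10b <- rg_of(strrep("G", 10), 99)
  r30 <- rg_of(strrep("G", 30), 1)
  expect_gt(r30, r10a * 1.4)
  expect_equal(r10a, r10b, tolerance = 0.1)
})
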