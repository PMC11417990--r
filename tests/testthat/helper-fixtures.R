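# Shared fixtures: force fields are cached per mode, and small relaxed
# frames are produced by short dynamics so that gradient checks run on
# physically sensible conformations.

ff_cache <- new.env()
get_ff <- function(mode, salt_mM = 150) {
  key <- paste(mode, salt_mM)
  if (is.null(ff_cache[[key]])) {
    ff_cache[[key]] <- default_forcefield(mode, salt_mM = salt_mM)
  }
  ff_cache[[key]]
}

# a short equilibration that returns the final frame of a small chain
relaxed_frame <- function(sequence, mode = "high_pH", seed = 5,
                          n_steps = 20000) {
  ff <- get_ff(mode)
  top <- build_chain(assign_protonation(sequence, mode), ff)
  tr <- simulate_chain(top, ff, n_steps = n_steps, output_every = n_steps,
                       seed = seed)
  list(coords = tr$coords, topology = top, forcefield = ff)
}

# build a minimal cg_trajectory around explicit frames (for analysis tests)
fake_trajectory <- function(frames, steps = seq_len(dim(frames)[3]),
                            codes = rep("G", dim(frames)[1]), replicate = 1L) {
  structure(list(frames = frames, steps = steps,
                 kinetic = rep(0, dim(frames)[3]),
                 coords = frames[, , dim(frames)[3]],
                 velocities = frames[, , dim(frames)[3]] * 0,
                 codes = codes,
                 settings = list(replicate = replicate, n_steps = max(steps),
                                 output_every = 1, seed = 0)),
            class = "cg_trajectory")
}

# central-difference gradient of the total energy
numerical_forces <- function(coords, top, ff, h = 1e-5, cutoffs = FALSE) {
  out <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (c in 1:3) {
      xp <- coords; xp[i, c] <- xp[i, c] + h
      xm <- coords; xm[i, c] <- xm[i, c] - h
      out[i, c] <- -(chain_energy(xp, top, ff, cutoffs = cutoffs)$total -
                     chain_energy(xm, top, ff, cutoffs = cutoffs)$total) / (2 * h)
    }
  }
  out
}
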